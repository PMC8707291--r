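---
title: "Methods: the peer-nomination analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the peer-nomination analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peernom)
```

## The data and its model

A classroom cohort consists of three tables. The **roster** lists each
learner with grade, gender and age. The **nominations** table records
reported bullying relations, each with a reporting mode: in a *peer*
nomination the nominator names a peer who bullied them; in a *self*
nomination the nominator confesses to bullying the nominee. The
**assessments** table holds, for learners who completed the effects
questionnaire, three ordinal items (content obscenity, impact,
frequency), each 1 = moderate, 2 = major, 3 = severe.

All analysis is within a class group: cross-grade nominations are
rejected by the validator, because the nomination instrument presents a
single class list and the resulting sociograms, roles and popularity
scores are only meaningful relative to that class. A roster spanning
several grades is split and processed per group; only the inferential
statistics (chi-square, ANOVA) pool across groups.

## The sociogram and its orientation

Both nomination kinds encode the same kind of relation — "the nominee
side bullied the victim side" — so they are merged into one simple
directed graph with every edge pointing **victim → accused bully**:
a peer nomination yields nominator → nominee, a self nomination yields
nominee → nominator. With this orientation the number of accusations a
learner *receives* (in-degree) and the PageRank mass that accrues to
them both measure prominence as a perpetrator, which is what
nomination-count popularity is meant to capture. The alternative
orientation (bully → victim) would concentrate PageRank on victims of
well-connected bullies, which answers a different question.

Two reports of the same ordered relation (the victim's accusation and
the bully's confession) collapse into one unweighted edge whose
provenance retains both records. The rules downstream are
existence-based ("nominated by one or more peers"), so edge
multiplicity carries no additional information; a weighted-graph mode
is deliberately out of scope. A learner confessing is represented by
the presence of a self-nomination, never by a self-loop, keeping the
graph simple and PageRank well-behaved.

## Role classification

Two predicates are evaluated per learner from the raw nominations (not
from the collapsed graph):

* **bully criterion** — made ≥ 1 self-nomination, or named as nominee
  in ≥ 1 peer nomination;
* **victim criterion** — made ≥ 1 peer nomination.

Both ⇒ `bully_victim`, bully only ⇒ `bully`, victim only ⇒ `victim`,
neither ⇒ `uninvolved`. Being named in a confession confers nothing:
the victim role requires the learner's *own* report.

The bully-victim clause admits a second reading in which any
self-nominating bully also counts as having "nominated a peer" and is
therefore promoted to bully-victim. Read that way, the pure-bully
category can only contain learners who were accused but never
confessed, and the two categories no longer partition cleanly along
the victim axis. The default here is the conjunction (bully criterion
**and** victim criterion), which keeps all four categories distinct;
the literal reading is available behind
`classify_roles(..., bully_victim_rule = "literal")` for sensitivity
analysis. The classifier is a pure predicate table, so results cannot
depend on nomination row order.

## Effects scoring

The rubric maps the item sum 3–9 to moderate (3–5), major (6–7),
severe (8–9), and any single item rated 3 forces severe. A consequence
worth knowing: the *major* level is reachable only by the single triple
(2,2,2), because any sum of 7 without a 3 is impossible and any triple
containing a 3 is overridden to severe. `override_applied` flags
exactly those severe assignments where the total alone would have said
moderate or major. Assessments with missing or out-of-range items are
rejected, not imputed — the rubric is undefined on partial input.

Effects are cross-tabulated for the roles that hold victim status
(bully-victims and victims). Assessments submitted by learners holding
other roles are not silently dropped: they surface in an
`other_assessed` residual row.

## Percentages in published-style tables

Counts are annotated with integer percentages by apportioning 100
percentage points over each row by largest remainder (ties to the
earlier column). Unlike per-cell rounding, this makes each row sum to
exactly 100 while keeping every cell within one point of its exact
share, and it reproduces the presentation convention of the field
tables this package mirrors — including rows where two equal counts
legitimately print as different percentages (e.g. 5/27 appearing as
both 19% and 18% in the same row).

## PageRank

Power iteration on the column-stochastic transition structure with
uniform teleportation: each sweep computes
r′ = (1 − d)/N + d (inflow + m/N) where inflow divides each node's
score equally over its out-edges and m is the total score held by
dangling nodes (learners who accuse nobody), redistributed uniformly.
Iteration stops when the L1 change drops below `tol` (default 1e-10,
far below any decision threshold downstream); exceeding `max_iter`
(default 1000) raises an error carrying the residual rather than
returning a silent partial result. For d < 1 the iteration is a
contraction, so convergence is guaranteed and the defaults are
generous. Damping d = 0.85 is the conventional choice and is exposed
as a parameter.

Raw scores sum to 1, which makes them shrink mechanically with class
size; N-scaled scores (raw × N, mean 1) are computed alongside and
used when pooling across classes. Published group means of 0.56–0.86
for this kind of data are consistent with neither normalization
(raw means are 1/N ≈ 0.02–0.04; N-scaled grand means are 1), so no
attempt is made to match them: the scaling behind them is not
recoverable, and orderings and group contrasts — everything the
analysis actually uses — are scaling-invariant. Ranked output uses
dense ranking (tied scores share a rank).

## Inferential statistics

The role-by-grade table is tested with the Pearson chi-square test of
independence without continuity correction (a Yates flag exists for
2×2 uses); a `low_expected` flag is set when any expected count falls
below 5, which happens in realistically small cohorts.

The two-way gender × grade ANOVA fits the full factorial model with
interaction; residual degrees of freedom are N − ab. For unbalanced
data (gender is never balanced within grades) the default is Type II
sums of squares — each main effect adjusted for the other, ignoring
the interaction — which is the conventional choice when no interaction
is hypothesised a priori; Type I (sequential) and Type III
(sum-to-zero contrasts, the SPSS default) are available, and all three
coincide on balanced designs. Two degenerate cases are reported
honestly rather than numerically: an empty design cell aborts with the
cell named (the interaction is inestimable), and a zero residual sum
of squares (constant response, or perfect separation by the factors)
sets an `f_undefined` flag, with the sums-of-squares decomposition in
that case computed by explicit nested-model comparison.

## The synthetic cohort generator

The generator emulates a class cohort under planted conditions: role
prevalences are converted to exact counts by largest-remainder
apportionment (ties by role order), demographics are sampled from the
configured gender split and age distribution (ages rounded to integer
years and truncated to the 10–30 plausibility band), and nominations
are constructed *rule-consistently*: every victim-side learner accuses
at least one planted bully-side peer; every bully-side learner is
guaranteed the bully criterion (confession with probability
`self_nomination_rate`, default 0.5, with receipt of an accusation as
fallback); planted uninvolved learners neither emit nor receive
anything. Extra accusations are added per victim-side learner with
Poisson(`mean_out_nominations` − 1) counts, default intensity 1.5 —
a free parameter, as nomination-count distributions for this
instrument are not published. Effects triples are drawn per role from
a configurable distribution over the 27 triples;
`effects_distribution_from_levels()` builds one from target severity
proportions by spreading each level's mass uniformly over the triples
the rubric maps there. The default profile draws items independently
with probabilities (0.5, 0.3, 0.2).

Two presets, `table5_grade10` (N = 52) and `table5_grade12` (N = 27),
carry the role prevalences, gender splits, age distributions and
per-role severity profiles of a published two-class field deployment,
so that classify → crosstab on a generated preset reproduces that
deployment's role counts and percentages exactly.

Rule-consistent construction makes planted-role recovery exact by
design — `recovery_check()` verifies it, and the test suite does so
across 100 seeds per preset. This is a *consistency* property, not a
validation against real behaviour: the generator has no reciprocity,
no popularity feedback, no homophily, and independence between a
learner's role and their demographics. Passing tests therefore show
that the pipeline's stages compose correctly and invert the
generator's planting, not that the classifier is accurate on real
classrooms, where reporting is incomplete and asymmetric. The
adversarial mode (`rule_consistent = FALSE`) produces random
nomination patterns for exercising the confusion-matrix path.

## Problem sizes and determinism

The test suite works at the scale the methods are meant for: cohorts
of 27–52 learners, exhaustive enumeration where the space is small
(all 27 rubric triples; all nomination subsets on 2–3 learners, 200
random subsets on 4), 100 random digraphs of ≤ 6 nodes against a dense
linear-system PageRank oracle at 1e-8, one 10,000-learner cohort for
distributional convergence of generated severity levels (±2%), and
200 seeded recovery runs. The generator restores the caller's RNG
state, and identical configuration plus seed yields byte-identical CSV
output.

## Known limitations

* Pseudonymization uses a keyed FNV-1a hash: stable and salt-dependent,
  but not a cryptographic primitive; for adversarial threat models a
  keyed cryptographic hash should replace it.
* Nominations are unweighted and atemporal; repeated reports collapse.
* The effects rubric is taken as given; no psychometric validation is
  attempted.
* PageRank group means are not comparable to published absolute values
  (scaling unrecoverable, above); only relative statements are
  supported.
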