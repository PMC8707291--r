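# peernom

Peer-nomination sociometry for school classes: identify cyberbullying
roles, score the severity of cyberbullying effects, and rank learners by
cyberbullying popularity.

## The problem

School-based reporting tools collect two kinds of nomination from
learners in a class: a **peer nomination**, in which a learner names a
peer who bullied them, and a **self-nomination**, in which a learner
confesses to bullying a named peer. From these, together with a short
effects questionnaire, a class report can be assembled that tells
teachers and social workers *who* is involved (and how), *how badly*
victims are affected, and *which* perpetrators are most prominent.
`peernom` implements that analytic pipeline for researchers and
practitioners working with classroom nomination data, with a seeded
synthetic-cohort generator so every stage can be exercised and tested
without access to real (and necessarily confidential) data.

## The methods

**Roles.** Each learner receives exactly one role from two predicates
over the nominations. The *bully criterion* holds if the learner made at
least one self-nomination or was named in at least one peer nomination;
the *victim criterion* holds if the learner made at least one peer
nomination. Both criteria ⇒ *bully-victim*; bully only ⇒ *bully*; victim
only ⇒ *victim*; neither ⇒ *uninvolved*.

**Effects.** Three ordinal items — content obscenity, impact, frequency
— each scored 1 (moderate), 2 (major) or 3 (severe). The sum
*s* ∈ {3,…,9} is banded moderate (3–5), major (6–7), severe (8–9), with
an override: any single item rated 3 forces the severe level regardless
of *s*.

**Popularity.** Nominations define a directed sociogram with every edge
pointing victim → accused bully, so in-degree counts accusations
received. Popularity is the PageRank vector **r** solving

&nbsp;&nbsp;&nbsp;&nbsp;**r** = (1 − d)/N · **1** + d (P<sup>T</sup>**r** + m<sub>dangling</sub>/N · **1**)

computed by power iteration with uniform teleportation, uniform
redistribution of dangling-node mass, damping d = 0.85 and an L1
convergence tolerance of 1e-10. Scores are reported raw (summing to 1)
and N-scaled (averaging 1, comparable across class sizes).

**Group comparison.** Role-by-grade contingency tables are tested with
the Pearson chi-square test of independence (no continuity correction);
pooled popularity scores are compared with a two-way gender × grade
ANOVA with interaction (Type II sums of squares by default; Types I and
III available).

## Worked example

Simulate a two-class school (a grade-10 cohort of 52 and a grade-12
cohort of 27, with planted role prevalences matching a published field
deployment) and run the whole pipeline:

```r
library(peernom)

c10 <- generate_cohort(preset_cohort_config("table5_grade10", seed = 1))
c12 <- generate_cohort(preset_cohort_config("table5_grade12", seed = 1))
school <- cohort(rbind(c10$learners, c12$learners),
                 rbind(c10$nominations, c12$nominations),
                 rbind(c10$assessments, c12$assessments))
report <- run_pipeline(school)
report
#> <cohort_report> 79 learners, 2 grade group(s)
#> <role_crosstab> counts (percent)
#>       bully bully_victim   victim uninvolved
#> 10 11 (21%)     17 (33%) 10 (19%)   14 (27%)
#> 12  5 (19%)     14 (52%)  3 (11%)    5 (18%)
#> Chi-square test of independence: X2(3) = 2.957, p = 0.3982  [warning: expected count < 5]
```

The role crosstab says 17 of the 52 grade-10 learners (33%) are
bully-victims, 10 (19%) are victims, and so on; the chi-square test
finds no significant difference in role composition between the two
grades. Effects and popularity blocks:

```r
report$effects_crosstab[["10"]]
#> <effects_crosstab> counts (percent)
#>              moderate  major  severe
#> bully_victim  9 (53%) 0 (0%) 8 (47%)
#> victim        6 (60%) 0 (0%) 4 (40%)

report$anova
#> Two-way ANOVA (Type II sums of squares)
#> # A tibble: 4 x 6
#>   term           sum_sq    df  mean_sq statistic p_value
#> 1 gender       0.0221       1 0.0221    0.0539     0.817
#> 2 grade        0.000295     1 0.000295  0.000720   0.979
#> 3 interaction  0.911        1 0.911     2.23       0.140
#> 4 residual    30.7         75 0.409    NA         NA

head(report$per_learner[order(report$per_learner$rank),
                        c("learner_id", "grade", "role",
                          "pagerank_n_scaled", "in_degree", "rank")], 3)
#>   learner_id grade role         pagerank_n_scaled in_degree  rank
#> 1 G10-L049   10    bully_victim              2.52         3     1
#> 2 G12-L009   12    bully_victim              3.89         5     1
#> 3 G10-L033   10    bully                     2.39         3     2
```

The top-ranked learners in each grade hold roughly 2.5–3.9× the average
share of accusation mass — the priority targets for intervention.
Reports can be pseudonymized before sharing
(`pseudonymize(report, salt = "...")`) and written with
`write_report_json()` / `write_report_csv()`.

A thin command-line driver with `simulate`, `classify`, `effects`,
`popularity`, `stats` and `report` subcommands is installed at
`exec/peernom`.

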