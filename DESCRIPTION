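Package: peernom
Title: Peer-Nomination Sociometry for Cyberbullying Roles, Effects and Popularity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyses classroom peer- and self-nomination data to identify
    cyberbullying roles (bully, bully-victim, victim, uninvolved), score the
    severity of cyberbullying effects with a three-item ordinal rubric and a
    severe-override rule, rank learners by cyberbullying popularity using
    PageRank over the nomination sociogram, and compare groups with a
    chi-square test of independence and a two-way (gender x grade) analysis
    of variance. Includes a seeded generator of rule-consistent synthetic
    classroom cohorts with planted roles so the full pipeline is testable
    without access to real nomination data, plus a report driver with
    keyed-hash pseudonymization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    car,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
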