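role_of <- function(rt, id) {
  as.character(rt$assignments$role[rt$assignments$learner_id == id])
}

test_that("the four role rules assign the documented roles", {
  # accusation: nominator is the victim, nominee the bully
  rt <- classify_roles(mk_cohort(c("A", "B"), nom_rows(c("A", "B", "peer"))))
  expect_equal(role_of(rt, "A"), "victim")
  expect_equal(role_of(rt, "B"), "bully")

  # no activity at all
  rt <- classify_roles(mk_cohort(c("C")))
  expect_equal(role_of(rt, "C"), "uninvolved")

  # accused and accusing: bully-victim
  rt <- classify_roles(mk_cohort(c("A", "B", "D"),
                                 nom_rows(c("A", "B", "peer"),
                                          c("D", "A", "peer"))))
  expect_equal(role_of(rt, "A"), "bully_victim")
  expect_equal(role_of(rt, "B"), "bully")
  expect_equal(role_of(rt, "D"), "victim")

  # a confession marks the confessor a bully; the named peer gets nothing
  rt <- classify_roles(mk_cohort(c("A", "B"), nom_rows(c("A", "B", "self"))))
  expect_equal(role_of(rt, "A"), "bully")
  expect_equal(role_of(rt, "B"), "uninvolved")
})

test_that("the literal bully-victim reading promotes confessing bullies", {
  ch <- mk_cohort(c("A", "B"), nom_rows(c("A", "B", "self")))
  expect_equal(role_of(classify_roles(ch, "and"), "A"), "bully")
  expect_equal(role_of(classify_roles(ch, "literal"), "A"), "bully_victim")
})

test_that("classification matches the brute-force predicate oracle on all small cohorts", {
  # exhaustive over every nomination subset for 2 and 3 learners,
  # random subsets for 4
  for (n in 2:3) {
    ids <- LETTERS[seq_len(n)]
    pairs <- expand.grid(a = ids, b = ids, k = c("peer", "self"),
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$a != pairs$b, ]
    n_pool <- nrow(pairs)
    for (mask in 0:(2^n_pool - 1)) {
      sel <- which(bitwAnd(mask, 2^(seq_len(n_pool) - 1)) > 0)
      noms <- if (length(sel) > 0) {
        data.frame(nominator_id = pairs$a[sel], nominee_id = pairs$b[sel],
                   kind = pairs$k[sel])
      } else NULL
      rt <- classify_roles(mk_cohort(ids, noms))
      expected <- brute_force_roles(ids, noms)
      expect_equal(setNames(as.character(rt$assignments$role),
                            rt$assignments$learner_id),
                   expected)
    }
  }
  set.seed(11)
  ids <- LETTERS[1:4]
  pairs <- expand.grid(a = ids, b = ids, k = c("peer", "self"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, ]
  for (i in 1:200) {
    sel <- which(stats::runif(nrow(pairs)) < 0.25)
    noms <- if (length(sel) > 0) {
      data.frame(nominator_id = pairs$a[sel], nominee_id = pairs$b[sel],
                 kind = pairs$k[sel])
    } else NULL
    rt <- classify_roles(mk_cohort(ids, noms))
    expect_equal(setNames(as.character(rt$assignments$role),
                          rt$assignments$learner_id),
                 brute_force_roles(ids, noms))
  }
})

test_that("every learner gets exactly one role and counts partition the cohort", {
  set.seed(5)
  ids <- LETTERS[1:8]
  for (i in 1:20) {
    k <- sample(0:10, 1)
    noms <- if (k > 0) {
      do.call(nom_rows, lapply(seq_len(k), function(j) {
        c(sample(ids, 2), sample(c("peer", "self"), 1))
      }))
    } else NULL
    rt <- classify_roles(mk_cohort(ids, noms))
    expect_equal(nrow(rt$assignments), length(ids))
    expect_false(anyNA(rt$assignments$role))
    expect_equal(sum(rt$counts), length(ids))
    expect_equal(sum(rt$percentages), 100L)
  }
})

test_that("adding a peer nomination never demotes nominator or nominee", {
  lattice <- c(uninvolved = 0, victim = 1, bully = 1, bully_victim = 2)
  victim_side <- c(victim = 1, bully_victim = 1, uninvolved = 0, bully = 0)
  bully_side <- c(bully = 1, bully_victim = 1, uninvolved = 0, victim = 0)
  set.seed(17)
  ids <- LETTERS[1:5]
  for (i in 1:30) {
    k <- sample(0:6, 1)
    noms <- if (k > 0) {
      do.call(nom_rows, lapply(seq_len(k), function(j) {
        c(sample(ids, 2), sample(c("peer", "self"), 1))
      }))
    } else NULL
    before <- classify_roles(mk_cohort(ids, noms))
    extra <- c(sample(ids, 2), "peer")
    noms2 <- rbind(noms, nom_rows(extra))
    after <- classify_roles(mk_cohort(ids, noms2))
    b <- setNames(as.character(before$assignments$role), ids)
    a <- setNames(as.character(after$assignments$role), ids)
    expect_true(all(lattice[a] >= lattice[b]))
    expect_gte(victim_side[a[extra[1]]], 1)  # nominator at least a victim
    expect_gte(bully_side[a[extra[2]]], 1)   # nominee at least a bully
  }
})

test_that("the roles crosstab reproduces published-style counts and percentages", {
  g10 <- classify_roles(generate_cohort(preset_cohort_config("table5_grade10",
                                                             seed = 4)))
  g12 <- classify_roles(generate_cohort(preset_cohort_config("table5_grade12",
                                                             seed = 4)))
  ct <- crosstab_roles(list("10" = g10, "12" = g12))
  expect_equal(unname(ct$counts["10", ]), c(11L, 17L, 10L, 14L))
  expect_equal(unname(ct$counts["12", ]), c(5L, 14L, 3L, 5L))
  expect_equal(unname(ct$percentages["10", ]), c(21L, 33L, 19L, 27L))
  expect_equal(unname(ct$percentages["12", ]), c(19L, 52L, 11L, 18L))
  expect_equal(unname(ct$n), c(52, 27))

  solo <- crosstab_roles(list(x = classify_roles(mk_cohort("A"))))
  expect_equal(unname(solo$counts[1, ]), c(0L, 0L, 0L, 1L))
  expect_equal(unname(solo$percentages[1, "uninvolved"]), 100L)
})
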