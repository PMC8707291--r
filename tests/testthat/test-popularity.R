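test_that("power iteration matches the dense linear-system oracle on random digraphs", {
  set.seed(101)
  worst <- 0
  for (i in 1:100) {
    g <- random_sociogram(sample(2:6, 1))
    pop <- pagerank_popularity(g)
    oracle <- dense_pagerank(g$nodes, g$edges)
    err <- max(abs(as.numeric(pop$pagerank_raw) - oracle))
    worst <- max(worst, err)
    expect_equal(sum(pop$pagerank_raw), 1, tolerance = 1e-9)
  }
  expect_lt(worst, 1e-8)
})

test_that("power iteration agrees with igraph's PageRank", {
  skip_if_not_installed("igraph")
  set.seed(33)
  for (i in 1:10) {
    g <- random_sociogram(5)
    pop <- pagerank_popularity(g)
    ig <- igraph::graph_from_data_frame(
      g$edges[c("source", "target")], directed = TRUE,
      vertices = data.frame(name = g$nodes))
    ref <- igraph::page_rank(ig, damping = 0.85)$vector[g$nodes]
    expect_equal(as.numeric(pop$pagerank_raw), as.numeric(ref),
                 tolerance = 1e-6)
  }
})

test_that("hand-solved small graphs score as expected", {
  # single accusation A -> B: solved from the 2-node stationary equations
  # with uniform dangling redistribution
  ch <- mk_cohort(c("A", "B"), nom_rows(c("A", "B", "peer")))
  # r_A = 0.075 + 0.425 r_B, r_B = 0.075 + 0.85 (r_A + r_B / 2)
  # => r_A = 0.5 / 1.425
  pop <- pagerank_popularity(build_sociogram(ch))
  expect_equal(unname(pop$pagerank_raw["A"]), 0.5 / 1.425, tolerance = 1e-7)
  expect_equal(unname(pop$pagerank_raw["A"]), 0.3508772, tolerance = 1e-6)
  expect_equal(unname(pop$pagerank_raw["B"]), 0.6491228, tolerance = 1e-6)

  # mutual accusations: symmetry forces an even split
  ch <- mk_cohort(c("A", "B"), nom_rows(c("A", "B", "peer"),
                                        c("B", "A", "peer")))
  pop <- pagerank_popularity(build_sociogram(ch))
  expect_equal(unname(pop$pagerank_raw), c(0.5, 0.5), tolerance = 1e-9)

  # no edges at all: uniform scores
  pop <- pagerank_popularity(build_sociogram(mk_cohort(LETTERS[1:4])))
  expect_equal(unname(pop$pagerank_raw), rep(0.25, 4), tolerance = 1e-12)
  expect_equal(unname(pop$pagerank_n_scaled), rep(1, 4), tolerance = 1e-12)
})

test_that("n-scaled scores average one and preserve ordering", {
  set.seed(7)
  g <- random_sociogram(6)
  pop <- pagerank_popularity(g, scaling = "n_scaled")
  expect_equal(mean(pop$pagerank_n_scaled), 1, tolerance = 1e-9)
  expect_equal(order(pop$pagerank_n_scaled), order(pop$pagerank_raw))
})

test_that("a new accusation never lowers the accused learner's score", {
  set.seed(59)
  for (i in 1:20) {
    g <- random_sociogram(5)
    pairs <- expand.grid(s = g$nodes, t = g$nodes, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$s != pairs$t, ]
    existing <- paste(g$edges$source, g$edges$target)
    free <- pairs[!(paste(pairs$s, pairs$t) %in% existing), ]
    if (nrow(free) == 0) next
    pick <- free[sample(nrow(free), 1), ]
    before <- pagerank_popularity(g)$pagerank_raw[[pick$t]]
    g2 <- g
    g2$edges <- rbind(g2$edges,
                      tibble::tibble(source = pick$s, target = pick$t,
                                     n_reports = 1L))
    after <- pagerank_popularity(g2)$pagerank_raw[[pick$t]]
    expect_gte(after, before - 1e-12)
  }
})

test_that("in-degree counts distinct accusations and ignores row order", {
  noms <- nom_rows(c("A", "B", "peer"), c("C", "B", "peer"),
                   c("B", "A", "self"), c("A", "B", "peer"))
  ch <- mk_cohort(c("A", "B", "C"), noms)
  deg <- sociogram_in_degree(build_sociogram(ch))
  # B is accused by A (peer, repeated), by C (peer) and by their own
  # confession naming A (all three A-side reports collapse to A -> B)
  expect_equal(deg, c(A = 0L, B = 2L, C = 0L))
  ch2 <- mk_cohort(c("A", "B", "C"), noms[c(3, 1, 4, 2), ])
  expect_equal(sociogram_in_degree(build_sociogram(ch2)), deg)
  pop <- pagerank_popularity(build_sociogram(ch))
  expect_equal(pop$in_degree, deg)
})

test_that("non-convergence raises an explicit error carrying the residual", {
  set.seed(3)
  g <- random_sociogram(5)
  expect_error(pagerank_popularity(g, max_iter = 1L),
               "did not converge.*residual")
  expect_error(pagerank_popularity(g, damping = 1), "damping")
})

test_that("dense ranking shares ranks among ties", {
  pop <- pagerank_popularity(build_sociogram(mk_cohort(LETTERS[1:3])))
  expect_equal(pop$table$rank, rep(1L, 3))
  ch <- mk_cohort(c("A", "B", "C"), nom_rows(c("A", "B", "peer")))
  tab <- pagerank_popularity(build_sociogram(ch))$table
  expect_equal(tab$rank[tab$learner_id == "B"], 1L)
  # A and C receive only teleport plus the dangling share, so they tie at 2
  expect_equal(tab$rank[tab$learner_id %in% c("A", "C")], c(2L, 2L))
})

test_that("group summaries use sample SD and report singletons as NA", {
  roster <- rbind(mk_roster(c("A", "B", "C"), gender = "female"),
                  mk_roster("D", gender = "male"))
  scores <- c(A = 1, B = 1, C = 1, D = 2)
  s <- summarize_popularity(scores, validate_roster(roster), by = "gender")
  f <- s[s$gender == "female", ]
  expect_equal(f$mean, 1)
  expect_equal(f$sd, 0)
  expect_true(is.na(s$sd[s$gender == "male"]))

  two <- summarize_popularity(c(A = 0, B = 1),
                              validate_roster(mk_roster(c("A", "B"))),
                              by = "grade")
  expect_equal(two$mean[1], 0.5)
  expect_equal(two$sd[1], sqrt(0.5), tolerance = 1e-12)

  # identical score multisets in two groups give identical summaries
  roster2 <- rbind(mk_roster(c("A", "B"), gender = "female"),
                   mk_roster(c("C", "D"), gender = "male"))
  s2 <- summarize_popularity(c(A = 0.2, B = 0.8, C = 0.8, D = 0.2),
                             validate_roster(roster2), by = "gender")
  expect_equal(s2$mean[s2$gender == "female"], s2$mean[s2$gender == "male"])
  expect_equal(s2$sd[s2$gender == "female"], s2$sd[s2$gender == "male"])

  expect_error(summarize_popularity(c(Z = 1), validate_roster(mk_roster("A"))),
               "missing from roster")
})
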