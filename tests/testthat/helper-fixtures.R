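# Shared fixture builders and independent oracles for the test suite.

mk_roster <- function(ids, grade = "10", gender = "female", age = 16L) {
  data.frame(learner_id = ids, grade = grade, gender = gender, age = age,
             stringsAsFactors = FALSE)
}

mk_cohort <- function(ids, noms = NULL, assessments = NULL, ...) {
  cohort(mk_roster(ids, ...), noms, assessments)
}

nom_rows <- function(...) {
  # nom_rows(c("A","B","peer"), c("B","A","self"))
  m <- do.call(rbind, list(...))
  data.frame(nominator_id = m[, 1], nominee_id = m[, 2], kind = m[, 3],
             stringsAsFactors = FALSE)
}

# Independent brute-force role oracle: literal predicate evaluation by
# looping over nomination records, no vectorised reuse of package code.
brute_force_roles <- function(ids, noms) {
  vapply(ids, function(id) {
    bully <- FALSE
    victim <- FALSE
    if (!is.null(noms) && nrow(noms) > 0) {
      for (i in seq_len(nrow(noms))) {
        if (noms$kind[i] == "self" && noms$nominator_id[i] == id) bully <- TRUE
        if (noms$kind[i] == "peer" && noms$nominee_id[i] == id) bully <- TRUE
        if (noms$kind[i] == "peer" && noms$nominator_id[i] == id) victim <- TRUE
      }
    }
    if (bully && victim) "bully_victim"
    else if (bully) "bully"
    else if (victim) "victim"
    else "uninvolved"
  }, "")
}

# Independent rubric oracle: direct transcription of the banded-sum rule
# with the severe override, evaluated one triple at a time.
brute_force_effects_level <- function(o, i, f) {
  s <- o + i + f
  if (o == 3 || i == 3 || f == 3) return("severe")
  if (s <= 5) "moderate" else if (s <= 7) "major" else "severe"
}

# Dense linear-system PageRank oracle: solve (I - d*M) r = (1-d)/n * 1
# where column i of M spreads node i's mass uniformly over its
# out-neighbours, or over all nodes when i is dangling.
dense_pagerank <- function(nodes, edges, damping = 0.85) {
  n <- length(nodes)
  M <- matrix(0, n, n)
  out_deg <- table(factor(edges$source, levels = nodes))
  for (i in seq_len(n)) {
    if (out_deg[i] == 0) {
      M[, i] <- 1 / n
    } else {
      tg <- match(edges$target[edges$source == nodes[i]], nodes)
      M[tg, i] <- 1 / out_deg[i]
    }
  }
  solve(diag(n) - damping * M, rep((1 - damping) / n, n))
}

# Seeded random simple digraph on n nodes as a sociogram-shaped fixture.
random_sociogram <- function(n, p = 0.35) {
  nodes <- LETTERS[seq_len(n)]
  pairs <- expand.grid(source = nodes, target = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  keep <- stats::runif(nrow(pairs)) < p
  edges <- tibble::tibble(source = pairs$source[keep],
                          target = pairs$target[keep],
                          n_reports = 1L)
  edges <- edges[order(edges$source, edges$target), ]
  structure(list(nodes = nodes, edges = edges,
                 provenance = vector("list", nrow(edges))),
            class = "sociogram")
}

# Explicit design-matrix least-squares ANOVA oracle for a two-level
# two-factor design: indicator columns built by hand, RSS via qr,
# sums of squares from residual-sum differences between nested models.
rss <- function(X, y) {
  beta <- qr.coef(qr(X), y)
  beta[is.na(beta)] <- 0
  sum((y - X %*% beta)^2)
}

design_matrix_anova <- function(y, a, b) {
  a <- as.integer(factor(a)) - 1L  # 0/1 indicators
  b <- as.integer(factor(b)) - 1L
  one <- rep(1, length(y))
  X1 <- cbind(one)
  XA <- cbind(one, a)
  XB <- cbind(one, b)
  XAB <- cbind(one, a, b)
  Xfull <- cbind(one, a, b, a * b)
  list(
    type1 = c(A = rss(X1, y) - rss(XA, y),
              B = rss(XA, y) - rss(XAB, y),
              AB = rss(XAB, y) - rss(Xfull, y)),
    type2 = c(A = rss(XB, y) - rss(XAB, y),
              B = rss(XA, y) - rss(XAB, y),
              AB = rss(XAB, y) - rss(Xfull, y)),
    residual = rss(Xfull, y))
}
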