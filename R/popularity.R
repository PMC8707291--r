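#' PageRank popularity over a nomination sociogram
#'
#' Computes the stationary distribution of a random surfer with uniform
#' teleportation on the victim -> bully sociogram by power iteration:
#' at every sweep a node's score is `(1 - d)/N` plus `d` times the mass
#' flowing in along edges (each node divides its score equally over its
#' out-edges) plus the uniform redistribution of the mass held by dangling
#' nodes (nodes with no out-edges). Iteration stops when the L1 change
#' between sweeps drops below `tol`. Because edges point at accused
#' bullies, PageRank mass accrues to learners frequently and prominently
#' accused — a popularity measure for cyberbullying behaviour.
#'
#' Raw scores sum to 1; `n_scaled` scores are raw times N so their mean is
#' 1, which makes scores comparable across class groups of different size.
#'
#' @param g A `"sociogram"`.
#' @param damping Probability of following an edge rather than teleporting;
#'   default 0.85, the conventional value.
#' @param tol L1 convergence tolerance; default 1e-10.
#' @param max_iter Maximum sweeps before aborting; default 1000.
#' @param scaling `"raw"` (scores sum to 1) or `"n_scaled"` (scores average
#'   1). Both are always returned; `scaling` selects which one the `score`
#'   column of ranked output reports.
#' @return Object of class `"popularity_scores"`: list with `pagerank`
#'   (named vector, selected scaling), `pagerank_raw`, `pagerank_n_scaled`,
#'   `in_degree`, `damping`, `scaling`, `iterations_used`, and `table` — a
#'   tibble `learner_id, pagerank_raw, pagerank_n_scaled, in_degree, rank`
#'   with dense ranking (ties share a rank) by decreasing score.
#' @export
pagerank_popularity <- function(g, damping = 0.85, tol = 1e-10,
                                max_iter = 1000L,
                                scaling = c("raw", "n_scaled")) {
  stopifnot(inherits(g, "sociogram"))
  scaling <- match.arg(scaling)
  if (!(damping > 0 && damping < 1)) {
    abort_validation("damping must lie strictly between 0 and 1")
  }
  n <- length(g$nodes)
  if (n == 0) abort_validation("sociogram has no nodes")

  src <- match(g$edges$source, g$nodes)
  tgt <- match(g$edges$target, g$nodes)
  out_deg <- tabulate(src, nbins = n)
  dangling <- out_deg == 0

  r <- rep(1 / n, n)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    contrib <- r[src] / out_deg[src]
    inflow <- as.numeric(tapply(contrib, factor(tgt, levels = seq_len(n)),
                                sum, default = 0))
    dangling_mass <- sum(r[dangling])
    r_new <- (1 - damping) / n + damping * (inflow + dangling_mass / n)
    delta <- sum(abs(r_new - r))
    r <- r_new
    if (delta < tol) break
    if (iter >= max_iter) {
      stop(sprintf(
        "PageRank power iteration did not converge in %d sweeps (L1 residual %.3e > tol %.3e)",
        max_iter, delta, tol), call. = FALSE)
    }
  }
  raw <- setNames(r, g$nodes)
  n_scaled <- raw * n
  in_deg <- sociogram_in_degree(g)
  score <- if (scaling == "raw") raw else n_scaled
  # dense ranking: equal scores share a rank, next distinct score gets rank+1
  rank <- match(-score, sort(unique(-score)))
  tab <- tibble::tibble(learner_id = g$nodes,
                        pagerank_raw = as.numeric(raw),
                        pagerank_n_scaled = as.numeric(n_scaled),
                        in_degree = as.integer(in_deg),
                        rank = as.integer(rank))
  structure(list(pagerank = score, pagerank_raw = raw,
                 pagerank_n_scaled = n_scaled, in_degree = in_deg,
                 damping = damping, scaling = scaling,
                 iterations_used = iter, table = tab),
            class = "popularity_scores")
}

#' @export
print.popularity_scores <- function(x, ...) {
  cat(sprintf("<popularity_scores> %d learners, damping %.2f, %s scaling, %d sweeps\n",
              length(x$pagerank), x$damping, x$scaling, x$iterations_used))
  print(utils::head(x$table[order(x$table$rank), ], 5))
  invisible(x)
}

#' Summarize popularity scores by grouping factors
#'
#' Mean, sample standard deviation (n - 1 denominator) and n of the
#' selected PageRank scaling, per cell of the grouping factors and per
#' marginal level of each factor, plus the grand total. Groups of size 1
#' report `NA` for the standard deviation rather than zero.
#'
#' @param scores A `"popularity_scores"` object, or a named numeric vector
#'   of per-learner scores.
#' @param roster Validated roster tibble covering every scored learner.
#' @param by Character vector of roster columns to group by, e.g.
#'   `c("gender", "grade")`.
#' @param scaling Which scaling to summarize when `scores` is a
#'   `"popularity_scores"` object; defaults to the object's own setting.
#' @return A tibble with the grouping columns (marginals carry `"total"`),
#'   `n`, `mean`, `sd`.
#' @export
summarize_popularity <- function(scores, roster, by = c("gender", "grade"),
                                 scaling = NULL) {
  if (inherits(scores, "popularity_scores")) {
    if (is.null(scaling)) scaling <- scores$scaling
    v <- if (scaling == "raw") scores$pagerank_raw else scores$pagerank_n_scaled
  } else {
    v <- scores
  }
  if (!all(names(v) %in% roster$learner_id)) {
    abort_validation("scored learner(s) missing from roster: %s",
                     paste(utils::head(setdiff(names(v), roster$learner_id), 3),
                           collapse = ", "))
  }
  stopifnot(all(by %in% names(roster)))
  df <- roster[match(names(v), roster$learner_id), by, drop = FALSE]
  df$score <- as.numeric(v)

  cell_summary <- function(d, labels) {
    tibble::tibble(!!!labels,
                   n = nrow(d),
                   mean = mean(d$score),
                   sd = if (nrow(d) > 1) stats::sd(d$score) else NA_real_)
  }
  rows <- list()
  # full cells
  cells <- df |> dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$score),
                     sd = ifelse(dplyr::n() > 1, stats::sd(.data$score), NA_real_),
                     .groups = "drop")
  rows[[1]] <- cells
  # marginal over each single factor (redundant when only one factor)
  for (f in if (length(by) > 1) by else character()) {
    marg <- df |> dplyr::group_by(dplyr::across(dplyr::all_of(f))) |>
      dplyr::summarise(n = dplyr::n(), mean = mean(.data$score),
                       sd = ifelse(dplyr::n() > 1, stats::sd(.data$score), NA_real_),
                       .groups = "drop")
    for (other in setdiff(by, f)) marg[[other]] <- "total"
    rows[[length(rows) + 1]] <- marg[c(by, "n", "mean", "sd")]
  }
  grand <- cell_summary(df, setNames(as.list(rep("total", length(by))), by))
  rows[[length(rows) + 1]] <- grand
  dplyr::bind_rows(rows)
}
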