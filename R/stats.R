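#' Pearson chi-square test of independence
#'
#' Tests independence of the row and column classifications of a
#' contingency table of counts (for the pipeline: cyberbullying role by
#' grade group). Expected counts are `row total x column total / grand
#' total`; the statistic is `sum((O - E)^2 / E)` with `df = (r-1)(c-1)`
#' and the p-value from the upper tail of the chi-square distribution.
#' No continuity correction is applied by default; `correct = TRUE`
#' enables the Yates correction for 2x2 tables.
#'
#' @param observed Integer matrix (or table) of counts, at least 2x2, no
#'   all-zero row or column.
#' @param correct Apply the Yates continuity correction (2x2 only)?
#'   Default `FALSE`.
#' @return Object of class `"chi_square_result"`: `statistic`, `df`,
#'   `p_value`, `expected` (matrix), `low_expected` (`TRUE` when any
#'   expected count is below 5 — the usual validity caution), `correct`.
#' @export
chi_square_independence <- function(observed, correct = FALSE) {
  observed <- as.matrix(observed)
  if (any(observed < 0) || any(observed != round(observed))) {
    abort_validation("observed counts must be non-negative integers")
  }
  if (nrow(observed) < 2 || ncol(observed) < 2) {
    abort_validation("need at least 2 rows and 2 columns")
  }
  if (any(rowSums(observed) == 0) || any(colSums(observed) == 0)) {
    abort_validation("all-zero row or column: expected counts undefined")
  }
  ht <- suppressWarnings(stats::chisq.test(observed, correct = correct))
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = unname(ht$p.value),
                 expected = ht$expected,
                 low_expected = any(ht$expected < 5),
                 correct = correct),
            class = "chi_square_result")
}

#' @export
print.chi_square_result <- function(x, ...) {
  cat(sprintf("Chi-square test of independence: X2(%d) = %.4g, p = %.4g%s\n",
              x$df, x$statistic, x$p_value,
              if (x$low_expected) "  [warning: expected count < 5]" else ""))
  invisible(x)
}

#' Two-way analysis of variance with interaction
#'
#' Fits the full factorial model `response ~ A * B` (for the pipeline:
#' PageRank score by gender and grade) and returns the ANOVA table for the
#' two main effects, the interaction, and residuals. For unbalanced data
#' the sums-of-squares decomposition matters: Type II (each main effect
#' adjusted for the other, ignoring the interaction) is the default;
#' Type I (sequential) and Type III (each term adjusted for all others,
#' sum-to-zero contrasts) are available. On balanced designs all three
#' agree. Residual degrees of freedom are `N - a*b` (one parameter per
#' cell).
#'
#' @param response Numeric response vector.
#' @param factor_a,factor_b Factors (or label vectors) of the same length
#'   as `response`, each with at least two observed levels; every cell of
#'   the a x b design must be non-empty, otherwise the interaction is
#'   inestimable and an error names the empty cell.
#' @param ss_type `"II"` (default), `"I"` or `"III"`.
#' @param a_label,b_label Names used for the two factors in the output.
#' @return Object of class `"anova_table"`: a tibble `term, sum_sq, df,
#'   mean_sq, statistic, p_value` with rows for the two factors, the
#'   interaction and residuals, plus attributes `ss_type` and
#'   `f_undefined` (`TRUE` when the residual mean square is zero or the
#'   response is constant, so F ratios are not finite).
#' @export
two_way_anova <- function(response, factor_a, factor_b,
                          ss_type = c("II", "I", "III"),
                          a_label = "factor_a", b_label = "factor_b") {
  ss_type <- match.arg(ss_type)
  response <- as.numeric(response)
  if (length(factor_a) != length(response) || length(factor_b) != length(response)) {
    abort_validation("response and both factors must have equal length")
  }
  if (anyNA(response) || anyNA(factor_a) || anyNA(factor_b)) {
    abort_validation("missing values are not allowed")
  }
  A <- factor(factor_a)
  B <- factor(factor_b)
  if (nlevels(A) < 2 || nlevels(B) < 2) {
    abort_validation("each factor needs at least 2 observed levels")
  }
  cell_n <- table(A, B)
  if (any(cell_n == 0)) {
    empty <- which(cell_n == 0, arr.ind = TRUE)[1, ]
    abort_validation("empty design cell (%s = %s, %s = %s): interaction inestimable",
                     a_label, levels(A)[empty[1]], b_label, levels(B)[empty[2]])
  }
  dat <- data.frame(y = response, A = A, B = B)
  full_rss <- sum(stats::residuals(stats::lm(y ~ A * B, data = dat))^2)
  degenerate <- full_rss <= 1e-12 * max(1, sum(response^2))
  if (ss_type == "I") {
    fit <- stats::lm(y ~ A * B, data = dat)
    tab <- stats::anova(fit)
    sum_sq <- tab[["Sum Sq"]]
    df <- tab[["Df"]]
    terms <- trimws(rownames(tab))
  } else if (!degenerate) {
    if (ss_type == "III") {
      fit <- stats::lm(y ~ A * B, data = dat,
                       contrasts = list(A = "contr.sum", B = "contr.sum"))
      tab <- car::Anova(fit, type = 3)
      tab <- tab[rownames(tab) != "(Intercept)", ]
    } else {
      fit <- stats::lm(y ~ A * B, data = dat)
      tab <- car::Anova(fit, type = 2)
    }
    sum_sq <- tab[["Sum Sq"]]
    df <- tab[["Df"]]
    terms <- trimws(rownames(tab))
  } else {
    # zero residual variance: car::Anova refuses; compute the identical
    # decomposition by explicit nested-model comparison
    sum_sq_terms <- if (ss_type == "II") {
      r <- function(f) sum(stats::residuals(stats::lm(f, data = dat))^2)
      ab <- r(y ~ A + B)
      c(r(y ~ B) - ab, r(y ~ A) - ab, ab - full_rss)
    } else {
      X <- stats::model.matrix(
        ~ A * B, dat, contrasts.arg = list(A = "contr.sum", B = "contr.sum"))
      asgn <- attr(X, "assign")
      rss_cols <- function(keep) {
        sum(qr.resid(qr(X[, keep, drop = FALSE]), dat$y)^2)
      }
      vapply(1:3, function(k) rss_cols(asgn != k) - full_rss, 0)
    }
    sum_sq <- c(sum_sq_terms, full_rss)
    df <- c(nlevels(A) - 1, nlevels(B) - 1,
            (nlevels(A) - 1) * (nlevels(B) - 1),
            length(response) - nlevels(A) * nlevels(B))
    terms <- c("A", "B", "A:B", "Residuals")
  }
  term_map <- c(A = a_label, B = b_label, `A:B` = "interaction",
                Residuals = "residual")
  out <- tibble::tibble(term = unname(term_map[terms]), sum_sq = sum_sq,
                        df = df, mean_sq = sum_sq / df)
  ms_res <- out$mean_sq[out$term == "residual"]
  df_res <- out$df[out$term == "residual"]
  out$statistic <- ifelse(out$term == "residual", NA_real_,
                          out$mean_sq / ms_res)
  out$p_value <- ifelse(out$term == "residual", NA_real_,
                        stats::pf(out$statistic, out$df, df_res,
                                  lower.tail = FALSE))
  ord <- match(c(a_label, b_label, "interaction", "residual"), out$term)
  out <- out[ord, ]
  f_undefined <- degenerate ||
    !all(is.finite(out$statistic[out$term != "residual"]))
  structure(out, class = c("anova_table", class(out)),
            ss_type = ss_type, f_undefined = f_undefined)
}

#' @export
print.anova_table <- function(x, ...) {
  cat(sprintf("Two-way ANOVA (Type %s sums of squares%s)\n",
              attr(x, "ss_type"),
              if (isTRUE(attr(x, "f_undefined"))) "; F undefined" else ""))
  NextMethod()
  invisible(x)
}
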