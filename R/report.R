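#' Keyed FNV-1a hash pseudonym
#'
#' Stable keyed hash of learner identifiers: two passes of 32-bit FNV-1a
#' over `salt|id` with different offset bases, rendered as 16 hex digits.
#' The same salt always yields the same pseudonyms; without the salt the
#' mapping is not practically recoverable for opaque ids, but the hash is
#' not cryptographic and should not be treated as such.
#'
#' @param ids Character vector of identifiers.
#' @param salt Non-empty secret string.
#' @return Character vector of pseudonyms (`"anon-"` + 16 hex digits).
#' @keywords internal
fnv1a_pseudonym <- function(ids, salt) {
  if (!is.character(salt) || length(salt) != 1 || nchar(salt) == 0) {
    abort_validation("salt must be a non-empty string")
  }
  fnv <- function(bytes, offset) {
    # 32-bit FNV-1a in double arithmetic; the multiply is split into
    # 16-bit halves so every intermediate stays exact below 2^53
    p <- 16777619
    h <- offset
    for (b in bytes) {
      h <- bitwXor(as.integer(h %% 2^31), b) +
        (h %/% 2^31) * 2^31  # b < 256, so xor touches only the low bits
      h1 <- h %/% 65536
      h0 <- h %% 65536
      h <- (((h1 * p) %% 65536) * 65536 + h0 * p) %% 4294967296
    }
    h
  }
  hex32 <- function(h) {
    sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
  }
  vapply(ids, function(id) {
    bytes <- as.integer(charToRaw(paste0(salt, "|", id)))
    paste0("anon-", hex32(fnv(bytes, 2166136261)), hex32(fnv(bytes, 40389)))
  }, "", USE.NAMES = FALSE)
}

#' Run the full nomination-analysis pipeline
#'
#' Executes every stage over one or more class groups: sociogram
#' construction, role classification, effects scoring, PageRank
#' popularity, the role and effects cross-tabs, and — when the cohort
#' spans at least two grade groups — the chi-square test of role-by-grade
#' independence and the two-way gender x grade ANOVA on pooled
#' (n-scaled) PageRank scores. Sociograms, roles and popularity are
#' always computed within a class group; only the inferential statistics
#' pool across groups. Any stage validation error aborts the run; a
#' partial report is never returned.
#'
#' @param x A `"cohort"` (may span several grades), or paths via
#'   [read_cohort()] beforehand.
#' @param damping,tol,max_iter,scaling Passed to [pagerank_popularity()].
#' @param ss_type Sums-of-squares type for the ANOVA (default `"II"`).
#' @param bully_victim_rule Passed to [classify_roles()].
#' @param verbose Print per-stage record counts to standard error.
#' @return Object of class `"cohort_report"`: list with `per_learner`
#'   (tibble: learner_id, grade, gender, role, effects level/total,
#'   pagerank raw + n_scaled, in_degree, rank), `role_crosstab`,
#'   `effects_crosstab` (per grade), `popularity_summary`, `chi_square`
#'   (NULL for a single group), `anova` (NULL unless >= 2 grades and both
#'   genders present), and `options`.
#' @export
run_pipeline <- function(x, damping = 0.85, tol = 1e-10, max_iter = 1000L,
                         scaling = c("raw", "n_scaled"), ss_type = "II",
                         bully_victim_rule = "and", verbose = FALSE) {
  stopifnot(inherits(x, "cohort"))
  scaling <- match.arg(scaling)
  say <- function(fmt, ...) {
    if (verbose) message(sprintf(fmt, ...))
  }
  groups <- split_cohort_by_grade(x)
  say("pipeline: %d learners in %d grade group(s)", nrow(x$learners),
      length(groups))

  role_tables <- list()
  effects_tabs <- list()
  per_learner <- list()
  for (g in names(groups)) {
    ch <- groups[[g]]
    soc <- build_sociogram(ch)
    say("grade %s: sociogram %d nodes, %d edges", g, length(soc$nodes),
        nrow(soc$edges))
    roles <- classify_roles(ch, bully_victim_rule = bully_victim_rule)
    pop <- pagerank_popularity(soc, damping = damping, tol = tol,
                               max_iter = max_iter, scaling = scaling)
    scored <- if (nrow(ch$assessments) > 0) {
      score_assessment(ch$assessments)
    } else {
      tibble::tibble(learner_id = character(), total = integer(),
                     level = factor(character(), levels = EFFECT_LEVELS),
                     override_applied = logical())
    }
    say("grade %s: %d roles assigned, %d assessments scored", g,
        nrow(roles$assignments), nrow(scored))
    role_tables[[g]] <- roles
    effects_tabs[[g]] <- crosstab_effects(roles, scored)

    pl <- ch$learners[c("learner_id", "grade", "gender")]
    pl$role <- as.character(roles$assignments$role[
      match(pl$learner_id, roles$assignments$learner_id)])
    m <- match(pl$learner_id, scored$learner_id)
    pl$effects_total <- scored$total[m]
    pl$effects_level <- as.character(scored$level)[m]
    pt <- pop$table
    mp <- match(pl$learner_id, pt$learner_id)
    pl$pagerank_raw <- pt$pagerank_raw[mp]
    pl$pagerank_n_scaled <- pt$pagerank_n_scaled[mp]
    pl$in_degree <- pt$in_degree[mp]
    pl$rank <- pt$rank[mp]
    per_learner[[g]] <- pl
  }
  per_learner <- dplyr::bind_rows(per_learner)

  role_ct <- crosstab_roles(role_tables)
  chi <- NULL
  if (length(groups) >= 2) {
    nonzero <- colSums(role_ct$counts) > 0
    chi <- chi_square_independence(role_ct$counts[, nonzero, drop = FALSE])
    say("chi-square: X2(%d) = %.3f", chi$df, chi$statistic)
  }
  pop_summary <- summarize_popularity(
    setNames(per_learner$pagerank_n_scaled, per_learner$learner_id),
    x$learners, by = c("gender", "grade"))
  aov_tab <- NULL
  if (length(groups) >= 2 &&
      length(unique(per_learner$gender)) >= 2 &&
      all(table(per_learner$gender, per_learner$grade) > 0)) {
    aov_tab <- two_way_anova(per_learner$pagerank_n_scaled,
                             per_learner$gender, per_learner$grade,
                             ss_type = ss_type,
                             a_label = "gender", b_label = "grade")
    say("anova: residual df %d", aov_tab$df[aov_tab$term == "residual"])
  }
  structure(list(per_learner = per_learner,
                 role_crosstab = role_ct,
                 effects_crosstab = effects_tabs,
                 popularity_summary = pop_summary,
                 chi_square = chi,
                 anova = aov_tab,
                 options = list(damping = damping, tol = tol,
                                max_iter = max_iter, scaling = scaling,
                                ss_type = ss_type,
                                bully_victim_rule = bully_victim_rule),
                 pseudonymized = FALSE),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d learners, %d grade group(s)%s\n",
              nrow(x$per_learner), nrow(x$role_crosstab$counts),
              if (x$pseudonymized) " [pseudonymized]" else ""))
  print(x$role_crosstab)
  if (!is.null(x$chi_square)) print(x$chi_square)
  invisible(x)
}

#' Pseudonymize a cohort report
#'
#' Replaces every learner identifier in the per-learner records with a
#' stable keyed hash of the identifier (see [fnv1a_pseudonym()]). The
#' id-to-pseudonym mapping is not kept in the report; re-identification
#' requires the salt. Summary blocks contain no identifiers and are
#' unchanged.
#'
#' @param report A `"cohort_report"`.
#' @param salt Non-empty secret string.
#' @return The report with pseudonymous `learner_id`s.
#' @export
pseudonymize <- function(report, salt) {
  stopifnot(inherits(report, "cohort_report"))
  report$per_learner$learner_id <-
    fnv1a_pseudonym(report$per_learner$learner_id, salt)
  report$pseudonymized <- TRUE
  report
}

crosstab_as_list <- function(ct) {
  list(counts = apply(ct$counts, 1, as.list, simplify = FALSE),
       percentages = apply(ct$percentages, 1, as.list, simplify = FALSE),
       n = as.list(ct$n))
}

#' Write a cohort report to canonical JSON
#'
#' Full-precision numeric fields plus display-rounded duplicates
#' (integer percentages, 2-decimal group means) in the summary blocks;
#' bit-stable for a fixed report and option set.
#'
#' @param report A `"cohort_report"`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "cohort_report"))
  pop <- report$popularity_summary
  pop$mean_2dp <- round(pop$mean, 2)
  pop$sd_2dp <- round(pop$sd, 2)
  payload <- list(
    per_learner = report$per_learner,
    role_crosstab = crosstab_as_list(report$role_crosstab),
    effects_crosstab = lapply(report$effects_crosstab, crosstab_as_list),
    popularity_summary = pop,
    chi_square = if (!is.null(report$chi_square)) {
      cs <- report$chi_square
      list(statistic = cs$statistic, df = cs$df, p_value = cs$p_value,
           low_expected = cs$low_expected, correct = cs$correct)
    },
    anova = if (!is.null(report$anova)) {
      list(table = as.data.frame(report$anova),
           ss_type = attr(report$anova, "ss_type"),
           f_undefined = attr(report$anova, "f_undefined"))
    },
    options = report$options,
    pseudonymized = report$pseudonymized,
    tool = list(package = "peernom",
                version = as.character(utils::packageVersion("peernom"))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Write the per-learner block of a report to CSV
#'
#' @param report A `"cohort_report"`.
#' @param path Output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  stopifnot(inherits(report, "cohort_report"))
  readr::write_csv(report$per_learner, path, na = "")
  invisible(path)
}
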