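EFFECT_LEVELS <- c("moderate", "major", "severe")

#' Score the three-item effects assessment
#'
#' Each of the three ordinal items (content obscenity, impact, frequency)
#' is coded 1 = moderate, 2 = major, 3 = severe. The total (3--9) is banded
#' as moderate (3--5), major (6--7) or severe (8--9), with one override:
#' if *any* single item is rated severe (3) the level is severe regardless
#' of the total. `override_applied` marks the cases where the override, not
#' the total, determined the level (some item = 3 while the total is below
#' the 8--9 severe band).
#'
#' @param obscenity,impact,frequency Integer vectors of equal length with
#'   values in 1--3 (recycled scalars allowed), or `obscenity` may be a
#'   validated assessment tibble with those three columns plus `learner_id`.
#' @return A tibble with columns `total` (integer 3--9), `level` (factor
#'   moderate < major < severe) and `override_applied` (logical), preceded
#'   by `learner_id` when an assessment table was given.
#' @export
score_assessment <- function(obscenity, impact = NULL, frequency = NULL) {
  learner_id <- NULL
  if (is.data.frame(obscenity)) {
    a <- obscenity
    stopifnot(all(c("obscenity", "impact", "frequency") %in% names(a)))
    learner_id <- a[["learner_id"]]
    obscenity <- a$obscenity
    impact <- a$impact
    frequency <- a$frequency
  }
  items <- cbind(obscenity, impact, frequency)
  if (any(is.na(items)) || !all(items %in% 1:3)) {
    abort_validation("assessment items must all be 1, 2 or 3; no missing values")
  }
  total <- as.integer(rowSums(items))
  any_severe <- apply(items == 3L, 1L, any)
  band <- cut(total, breaks = c(2, 5, 7, 9), labels = EFFECT_LEVELS)
  level <- factor(ifelse(any_severe, "severe", as.character(band)),
                  levels = EFFECT_LEVELS)
  override_applied <- any_severe & total < 8L
  out <- tibble::tibble(total = total, level = level,
                        override_applied = override_applied)
  if (!is.null(learner_id)) {
    out <- tibble::tibble(learner_id = learner_id, out)
  }
  out
}

#' Cross-tabulate effects levels by victim-side role
#'
#' Effects are reported for the roles that hold victim status
#' (bully-victims and victims), by severity level, with integer-percent
#' annotation per role row. Assessed learners who hold another role are
#' not dropped silently: their level counts surface in a residual
#' `"other_assessed"` row excluded from the percentage table's headline
#' rows.
#'
#' @param roles A `"role_table"` for the cohort.
#' @param scored A scored assessment tibble with `learner_id` and `level`
#'   (as returned by [score_assessment()] on an assessment table).
#' @return Object of class `"effects_crosstab"`: `counts` and
#'   `percentages` matrices with rows `bully_victim`, `victim` (and
#'   `other_assessed` when non-empty) and columns moderate/major/severe.
#' @export
crosstab_effects <- function(roles, scored) {
  stopifnot(inherits(roles, "role_table"))
  if (nrow(scored) > 0 && !("learner_id" %in% names(scored))) {
    abort_validation("scored assessments must carry learner_id")
  }
  unknown <- setdiff(scored$learner_id, roles$assignments$learner_id)
  if (length(unknown) > 0) {
    abort_validation("assessment for unknown learner '%s'", unknown[1])
  }
  role_of <- setNames(as.character(roles$assignments$role),
                      roles$assignments$learner_id)
  row_role <- role_of[scored$learner_id]
  row_role[!(row_role %in% c("bully_victim", "victim"))] <- "other_assessed"
  row_levels <- c("bully_victim", "victim", "other_assessed")
  counts <- table(factor(row_role, levels = row_levels),
                  factor(scored$level, levels = EFFECT_LEVELS))
  counts <- matrix(as.integer(counts), nrow = length(row_levels),
                   dimnames = list(row_levels, EFFECT_LEVELS))
  if (all(counts["other_assessed", ] == 0)) {
    counts <- counts[c("bully_victim", "victim"), , drop = FALSE]
  }
  n <- rowSums(counts)
  percentages <- counts
  for (i in seq_len(nrow(counts))) {
    percentages[i, ] <- percent_apportion(counts[i, ])
  }
  structure(list(counts = counts, percentages = percentages, n = n),
            class = "effects_crosstab")
}

#' @export
print.effects_crosstab <- function(x, ...) {
  cat("<effects_crosstab> counts (percent)\n")
  disp <- matrix(sprintf("%d (%d%%)", x$counts, x$percentages),
                 nrow = nrow(x$counts), dimnames = dimnames(x$counts))
  print(as.data.frame(disp))
  invisible(x)
}

#' Write scored effects to CSV
#'
#' @param scored Scored assessment tibble with `learner_id`.
#' @param path Output path; columns `learner_id,total,level,override_applied`.
#' @return `path`, invisibly.
#' @export
write_effects <- function(scored, path) {
  out <- scored[c("learner_id", "total", "level", "override_applied")]
  out$level <- as.character(out$level)
  readr::write_csv(out, path)
  invisible(path)
}
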