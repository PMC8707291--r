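ROLES <- c("bully", "bully_victim", "victim", "uninvolved")

#' Integer percentages by largest-remainder apportionment
#'
#' Table-style presentation percentages: 100 percentage points are
#' apportioned over the cells of a row by largest remainder (ties to the
#' earlier cell), so each row of a published-style table sums to exactly
#' 100 while every cell stays within one point of its exact share.
#'
#' @param counts Non-negative integer vector (one table row).
#' @return Integer percentage vector summing to 100 (all zeros if the
#'   row is empty).
#' @keywords internal
percent_apportion <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(setNames(rep(0L, length(counts)), names(counts)))
  largest_remainder(100L, counts / n)
}

#' Classify cyberbullying roles from nominations
#'
#' Each learner receives exactly one of four roles, evaluated from two
#' predicates over the cohort's nominations:
#'
#' * **bully criterion** — the learner made at least one *self* nomination
#'   (confessed to bullying a peer) **or** was named as nominee in at least
#'   one *peer* nomination (accused by a victim);
#' * **victim criterion** — the learner made at least one *peer* nomination
#'   (named a peer as their bully).
#'
#' Both criteria give `bully_victim`; only the bully criterion, `bully`;
#' only the victim criterion, `victim`; neither, `uninvolved`. Being named
#' as the nominee of a confession confers no role. Under
#' `bully_victim_rule = "literal"` the bully-victim clause instead reads
#' "meets the bully criterion and made any nomination at all", which
#' promotes every confessing bully to bully-victim; the default keeps the
#' four categories distinct.
#'
#' @param x A `"cohort"` object.
#' @param bully_victim_rule `"and"` (default: bully criterion AND victim
#'   criterion) or `"literal"` (bully criterion AND made >= 1 nomination of
#'   either kind).
#' @return An object of class `"role_table"`: list with `assignments`
#'   (tibble `learner_id,role`), `counts` (named integer vector over the
#'   four roles) and `percentages` (integer percents by largest-remainder
#'   apportionment, summing to 100).
#' @export
classify_roles <- function(x, bully_victim_rule = c("and", "literal")) {
  stopifnot(inherits(x, "cohort"))
  bully_victim_rule <- match.arg(bully_victim_rule)
  ids <- x$learners$learner_id
  nom <- x$nominations
  made_self <- ids %in% nom$nominator_id[nom$kind == "self"]
  named_peer <- ids %in% nom$nominee_id[nom$kind == "peer"]
  made_peer <- ids %in% nom$nominator_id[nom$kind == "peer"]
  bully_crit <- made_self | named_peer
  victim_crit <- made_peer
  bv <- if (bully_victim_rule == "and") {
    bully_crit & victim_crit
  } else {
    bully_crit & (made_peer | made_self)
  }
  role <- ifelse(bv, "bully_victim",
                 ifelse(bully_crit, "bully",
                        ifelse(victim_crit, "victim", "uninvolved")))
  assignments <- tibble::tibble(learner_id = ids,
                                role = factor(role, levels = ROLES))
  counts <- table(assignments$role)
  counts <- setNames(as.integer(counts), names(counts))
  n <- length(ids)
  percentages <- percent_apportion(counts)
  structure(list(assignments = assignments, counts = counts,
                 percentages = setNames(as.integer(percentages), names(counts)),
                 n = n, bully_victim_rule = bully_victim_rule),
            class = "role_table")
}

#' @export
print.role_table <- function(x, ...) {
  cat(sprintf("<role_table> N = %d\n", x$n))
  print(tibble::tibble(role = names(x$counts), count = x$counts,
                       percent = x$percentages))
  invisible(x)
}

#' Cross-tabulate roles across class groups
#'
#' Builds the grades x roles contingency table of role counts with
#' integer-percent annotation, the summary published for each class group.
#'
#' @param role_tables Named list of `"role_table"` objects (names are the
#'   grade labels), or a list of `list(grade =, roles =)` pairs.
#' @return An object of class `"role_crosstab"`: list with `counts`
#'   (matrix grades x roles), `percentages` (integer matrix; each row's
#'   percentages apportioned by largest remainder to sum to 100) and `n`
#'   (row totals).
#' @export
crosstab_roles <- function(role_tables) {
  stopifnot(length(role_tables) >= 1)
  if (is.null(names(role_tables)) || any(names(role_tables) == "")) {
    abort_validation("role_tables must be a named list (grade labels as names)")
  }
  counts <- do.call(rbind, lapply(role_tables, function(rt) rt$counts[ROLES]))
  rownames(counts) <- names(role_tables)
  colnames(counts) <- ROLES
  n <- rowSums(counts)
  percentages <- counts
  for (i in seq_len(nrow(counts))) {
    percentages[i, ] <- percent_apportion(counts[i, ])
  }
  structure(list(counts = counts, percentages = percentages, n = n),
            class = "role_crosstab")
}

#' @export
print.role_crosstab <- function(x, ...) {
  cat("<role_crosstab> counts (percent)\n")
  disp <- matrix(sprintf("%d (%d%%)", x$counts, x$percentages),
                 nrow = nrow(x$counts), dimnames = dimnames(x$counts))
  print(as.data.frame(disp))
  invisible(x)
}

#' Write per-learner role assignments to CSV
#'
#' @param roles A `"role_table"`.
#' @param path Output path; columns `learner_id,role`.
#' @return `path`, invisibly.
#' @export
write_roles <- function(roles, path) {
  stopifnot(inherits(roles, "role_table"))
  out <- roles$assignments
  out$role <- as.character(out$role)
  readr::write_csv(out, path)
  invisible(path)
}
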