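#' @importFrom rlang .data
#' @importFrom stats setNames
NULL

GENDERS <- c("female", "male", "unspecified")
NOMINATION_KINDS <- c("peer", "self")
AGE_PLAUSIBLE <- c(10L, 30L)

abort_validation <- function(msg, ...) {
  stop(sprintf(msg, ...), call. = FALSE)
}

#' Validate a class roster
#'
#' Checks a roster table for the invariants every downstream stage relies on:
#' unique, non-missing learner identifiers; a recognised gender label for each
#' learner; and, where age is present, values inside a school-age plausibility
#' band (a warning, not an error, is raised for ages outside 10--30).
#'
#' @param roster A data frame with columns `learner_id`, `grade`, `gender`,
#'   `age`. `learner_id` and `grade` are treated as opaque strings; `gender`
#'   must be one of `"female"`, `"male"`, `"unspecified"`; `age` may be `NA`.
#' @return A validated tibble with normalised column types.
#' @export
validate_roster <- function(roster) {
  required <- c("learner_id", "grade", "gender", "age")
  missing_cols <- setdiff(required, names(roster))
  if (length(missing_cols) > 0) {
    abort_validation("roster is missing column(s): %s",
                     paste(missing_cols, collapse = ", "))
  }
  roster <- tibble::as_tibble(roster)[required]
  roster$learner_id <- as.character(roster$learner_id)
  roster$grade <- as.character(roster$grade)
  roster$gender <- as.character(roster$gender)
  roster$age <- suppressWarnings(as.integer(roster$age))

  blank <- which(is.na(roster$learner_id) | roster$learner_id == "")
  if (length(blank) > 0) {
    abort_validation("roster row %d has a missing learner_id", blank[1])
  }
  dup <- which(duplicated(roster$learner_id))
  if (length(dup) > 0) {
    abort_validation("duplicate learner_id '%s' at roster row %d",
                     roster$learner_id[dup[1]], dup[1])
  }
  bad_gender <- which(!(roster$gender %in% GENDERS))
  if (length(bad_gender) > 0) {
    abort_validation(
      "roster row %d: unknown gender '%s' (allowed: %s)",
      bad_gender[1], roster$gender[bad_gender[1]],
      paste(GENDERS, collapse = ", "))
  }
  implausible <- which(!is.na(roster$age) &
                         (roster$age < AGE_PLAUSIBLE[1] | roster$age > AGE_PLAUSIBLE[2]))
  if (length(implausible) > 0) {
    warning(sprintf("roster row %d: age %d outside plausibility band [%d, %d]",
                    implausible[1], roster$age[implausible[1]],
                    AGE_PLAUSIBLE[1], AGE_PLAUSIBLE[2]), call. = FALSE)
  }
  roster
}

#' Read a class roster from CSV
#'
#' @param path Path to a CSV file with header `learner_id,grade,gender,age`.
#'   `age` may be blank.
#' @return A validated roster tibble (see [validate_roster()]).
#' @export
read_roster <- function(path) {
  if (!file.exists(path)) abort_validation("roster file not found: %s", path)
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  validate_roster(df)
}

#' Validate a nomination table against a roster
#'
#' A nomination records one reported bullying relation. In a *peer*
#' nomination the nominator names a peer who bullied them; in a *self*
#' nomination the nominator confesses to bullying the nominee. Endpoints
#' must exist in the roster, a learner cannot nominate themselves (a
#' confession is expressed by `kind = "self"`, never by a self-loop), and
#' nominations may not cross class/grade groups.
#'
#' @param nominations Data frame with columns `nominator_id`, `nominee_id`,
#'   `kind` (`"peer"` or `"self"`).
#' @param roster A validated roster tibble.
#' @return A validated nomination tibble.
#' @export
validate_nominations <- function(nominations, roster) {
  required <- c("nominator_id", "nominee_id", "kind")
  missing_cols <- setdiff(required, names(nominations))
  if (length(missing_cols) > 0) {
    abort_validation("nominations table is missing column(s): %s",
                     paste(missing_cols, collapse = ", "))
  }
  nom <- tibble::as_tibble(nominations)[required]
  nom$nominator_id <- as.character(nom$nominator_id)
  nom$nominee_id <- as.character(nom$nominee_id)
  nom$kind <- as.character(nom$kind)

  bad_kind <- which(!(nom$kind %in% NOMINATION_KINDS))
  if (length(bad_kind) > 0) {
    abort_validation("nomination row %d: kind '%s' not allowed (allowed: %s)",
                     bad_kind[1], nom$kind[bad_kind[1]],
                     paste(NOMINATION_KINDS, collapse = ", "))
  }
  known <- roster$learner_id
  bad_ref <- which(!(nom$nominator_id %in% known) | !(nom$nominee_id %in% known))
  if (length(bad_ref) > 0) {
    i <- bad_ref[1]
    unknown <- setdiff(c(nom$nominator_id[i], nom$nominee_id[i]), known)
    abort_validation("nomination row %d references unknown learner '%s'",
                     i, unknown[1])
  }
  loops <- which(nom$nominator_id == nom$nominee_id)
  if (length(loops) > 0) {
    abort_validation(
      "nomination row %d: a learner cannot nominate themselves (use kind = 'self' to record a confession)",
      loops[1])
  }
  grade_of <- setNames(roster$grade, roster$learner_id)
  cross <- which(grade_of[nom$nominator_id] != grade_of[nom$nominee_id])
  if (length(cross) > 0) {
    abort_validation(
      "nomination row %d crosses class groups ('%s' is grade %s, '%s' is grade %s); sociograms are per class",
      cross[1], nom$nominator_id[cross[1]], grade_of[nom$nominator_id[cross[1]]],
      nom$nominee_id[cross[1]], grade_of[nom$nominee_id[cross[1]]])
  }
  nom
}

#' Read a nomination table from CSV
#'
#' @param path CSV with header `nominator_id,nominee_id,kind`.
#' @param roster A validated roster tibble (loaded first).
#' @return A validated nomination tibble.
#' @export
read_nominations <- function(path, roster) {
  if (!file.exists(path)) abort_validation("nominations file not found: %s", path)
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  validate_nominations(df, roster)
}

#' Validate an effects-assessment table
#'
#' Each assessment holds the three ordinal rubric items (content obscenity,
#' impact, frequency), each coded 1 = moderate, 2 = major, 3 = severe. An
#' assessment with any missing or out-of-range item is rejected rather than
#' imputed: the severity rubric is undefined on partial input. At most one
#' assessment per learner is accepted.
#'
#' @param assessments Data frame with columns `learner_id`, `obscenity`,
#'   `impact`, `frequency`.
#' @param roster A validated roster tibble.
#' @return A validated assessment tibble with integer items.
#' @export
validate_assessments <- function(assessments, roster) {
  required <- c("learner_id", "obscenity", "impact", "frequency")
  missing_cols <- setdiff(required, names(assessments))
  if (length(missing_cols) > 0) {
    abort_validation("assessments table is missing column(s): %s",
                     paste(missing_cols, collapse = ", "))
  }
  a <- tibble::as_tibble(assessments)[required]
  a$learner_id <- as.character(a$learner_id)
  for (item in c("obscenity", "impact", "frequency")) {
    v <- suppressWarnings(as.integer(a[[item]]))
    bad <- which(is.na(v) | !(v %in% 1:3))
    if (length(bad) > 0) {
      abort_validation("assessment row %d: item '%s' must be 1, 2 or 3 (got '%s')",
                       bad[1], item, as.character(a[[item]][bad[1]]))
    }
    a[[item]] <- v
  }
  unknown <- which(!(a$learner_id %in% roster$learner_id))
  if (length(unknown) > 0) {
    abort_validation("assessment row %d references unknown learner '%s'",
                     unknown[1], a$learner_id[unknown[1]])
  }
  dup <- which(duplicated(a$learner_id))
  if (length(dup) > 0) {
    abort_validation("duplicate assessment for learner '%s' at row %d",
                     a$learner_id[dup[1]], dup[1])
  }
  a
}

#' Read an effects-assessment table from CSV
#'
#' @param path CSV with header `learner_id,obscenity,impact,frequency`.
#' @param roster A validated roster tibble.
#' @return A validated assessment tibble.
#' @export
read_assessments <- function(path, roster) {
  if (!file.exists(path)) abort_validation("assessments file not found: %s", path)
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  validate_assessments(df, roster)
}

#' Assemble a cohort
#'
#' A cohort bundles one class group's roster, nominations and effects
#' assessments with referential integrity enforced across the three tables.
#' Learners with no nominations and no assessment stay in the cohort; they
#' are the "uninvolved" denominators of every report.
#'
#' @param roster Roster data frame (see [validate_roster()]).
#' @param nominations Optional nomination data frame; default none.
#' @param assessments Optional assessment data frame; default none.
#' @return An object of class `"cohort"`: a list with validated tibbles
#'   `learners`, `nominations`, `assessments`.
#' @export
cohort <- function(roster, nominations = NULL, assessments = NULL) {
  learners <- validate_roster(roster)
  if (is.null(nominations)) {
    nominations <- tibble::tibble(nominator_id = character(),
                                  nominee_id = character(),
                                  kind = character())
  }
  if (is.null(assessments)) {
    assessments <- tibble::tibble(learner_id = character(),
                                  obscenity = integer(),
                                  impact = integer(),
                                  frequency = integer())
  }
  structure(
    list(learners = learners,
         nominations = validate_nominations(nominations, learners),
         assessments = validate_assessments(assessments, learners)),
    class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d learners (grades: %s), %d nominations, %d assessments\n",
              nrow(x$learners),
              paste(sort(unique(x$learners$grade)), collapse = ", "),
              nrow(x$nominations), nrow(x$assessments)))
  invisible(x)
}

#' Read a cohort from its three CSV files
#'
#' @param roster_path,nominations_path,assessments_path File paths; the
#'   nomination and assessment files are optional (`NULL` for none).
#' @return A `"cohort"` object.
#' @export
read_cohort <- function(roster_path, nominations_path = NULL,
                        assessments_path = NULL) {
  roster <- read_roster(roster_path)
  nominations <- if (!is.null(nominations_path)) {
    read_nominations(nominations_path, roster)
  }
  assessments <- if (!is.null(assessments_path)) {
    read_assessments(assessments_path, roster)
  }
  cohort(roster, nominations, assessments)
}

#' Split a multi-grade cohort into per-class cohorts
#'
#' Sociograms, roles and popularity are computed within a class group;
#' this helper splits a roster spanning several grades into one cohort per
#' grade label. Nominations never cross grades (the validator rejects them),
#' so the split is lossless.
#'
#' @param x A `"cohort"` object.
#' @return A named list of `"cohort"` objects, one per grade label.
#' @export
split_cohort_by_grade <- function(x) {
  stopifnot(inherits(x, "cohort"))
  grades <- sort(unique(x$learners$grade))
  grade_of <- setNames(x$learners$grade, x$learners$learner_id)
  out <- lapply(grades, function(g) {
    learners <- x$learners[x$learners$grade == g, ]
    noms <- x$nominations[grade_of[x$nominations$nominator_id] == g, ]
    asmt <- x$assessments[grade_of[x$assessments$learner_id] == g, ]
    cohort(learners, noms, asmt)
  })
  setNames(out, grades)
}

#' Build the nomination sociogram
#'
#' Constructs a simple directed graph over the cohort's learners in which
#' every edge points from the victim side toward the accused bully:
#' a *peer* nomination (nominator names their bully) yields the edge
#' nominator -> nominee, and a *self* nomination (nominator confesses to
#' bullying the nominee) yields nominee -> nominator. In-degree therefore
#' counts distinct accusations of bullying received. Nominations encoding
#' the same ordered relation collapse into one unweighted edge whose
#' provenance retains every contributing record; self-loops cannot arise
#' (the validator forbids nominator = nominee).
#'
#' @param x A `"cohort"` object.
#' @return An object of class `"sociogram"`: list with `nodes` (all roster
#'   learner ids, including isolated learners), `edges` (tibble
#'   `source,target,n_reports`) and `provenance` (list of contributing
#'   nomination tibbles, parallel to `edges` rows).
#' @export
build_sociogram <- function(x) {
  stopifnot(inherits(x, "cohort"))
  nodes <- x$learners$learner_id
  nom <- x$nominations
  if (nrow(nom) == 0) {
    return(structure(list(nodes = nodes,
                          edges = tibble::tibble(source = character(),
                                                 target = character(),
                                                 n_reports = integer()),
                          provenance = list()),
                     class = "sociogram"))
  }
  source <- ifelse(nom$kind == "peer", nom$nominator_id, nom$nominee_id)
  target <- ifelse(nom$kind == "peer", nom$nominee_id, nom$nominator_id)
  key <- paste(source, target, sep = "\r")
  ord <- order(source, target)
  ukey <- unique(key[ord])
  idx <- split(seq_len(nrow(nom)), factor(key, levels = ukey))
  edges <- tibble::tibble(
    source = vapply(strsplit(ukey, "\r", fixed = TRUE), `[`, "", 1L),
    target = vapply(strsplit(ukey, "\r", fixed = TRUE), `[`, "", 2L),
    n_reports = unname(vapply(idx, length, 0L)))
  provenance <- lapply(idx, function(i) nom[i, ])
  structure(list(nodes = nodes, edges = edges,
                 provenance = unname(provenance)),
            class = "sociogram")
}

#' @export
print.sociogram <- function(x, ...) {
  cat(sprintf("<sociogram> %d nodes, %d edges (victim -> bully)\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' In-degree of every learner in a sociogram
#'
#' The number of distinct victim -> bully accusation edges received; the
#' simple nomination-count popularity measure.
#'
#' @param g A `"sociogram"`.
#' @return Named integer vector over all nodes (zeros included).
#' @export
sociogram_in_degree <- function(g) {
  stopifnot(inherits(g, "sociogram"))
  counts <- table(factor(g$edges$target, levels = g$nodes))
  setNames(as.integer(counts), g$nodes)
}

#' Write a sociogram to an edge-list CSV
#'
#' Columns `source_id,target_id,n_reports`. Edges are written in sorted
#' order so that output is byte-stable for a given graph.
#'
#' @param g A `"sociogram"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sociogram <- function(g, path) {
  stopifnot(inherits(g, "sociogram"))
  e <- g$edges[order(g$edges$source, g$edges$target), ]
  readr::write_csv(tibble::tibble(source_id = e$source, target_id = e$target,
                                  n_reports = e$n_reports), path)
  invisible(path)
}

#' Read a sociogram from an edge-list CSV
#'
#' @param path Edge-list CSV written by [write_sociogram()].
#' @param nodes Optional character vector of node ids (to restore isolated
#'   learners the edge list cannot carry); defaults to the ids appearing in
#'   the edges.
#' @return A `"sociogram"` (provenance is not stored in the CSV and comes
#'   back as `NULL` entries).
#' @export
read_sociogram <- function(path, nodes = NULL) {
  df <- readr::read_csv(path, col_types = readr::cols(
    source_id = readr::col_character(),
    target_id = readr::col_character(),
    n_reports = readr::col_integer()))
  if (is.null(nodes)) nodes <- sort(unique(c(df$source_id, df$target_id)))
  if (!all(c(df$source_id, df$target_id) %in% nodes)) {
    abort_validation("edge list references nodes absent from 'nodes'")
  }
  edges <- tibble::tibble(source = df$source_id, target = df$target_id,
                          n_reports = df$n_reports)
  edges <- edges[order(edges$source, edges$target), ]
  structure(list(nodes = nodes, edges = edges,
                 provenance = vector("list", nrow(edges))),
            class = "sociogram")
}
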