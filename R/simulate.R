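#' Largest-remainder apportionment of a cohort into role counts
#'
#' Converts role prevalences into exact integer counts summing to `n`:
#' each role gets the floor of `n * p`, and the leftover units go to the
#' roles with the largest fractional remainders, ties broken by role
#' order (bully, bully_victim, victim, uninvolved). This makes preset
#' cohort compositions exactly reproducible.
#'
#' @param n Cohort size.
#' @param probs Numeric vector of proportions summing to 1 (names kept).
#' @return Integer vector of counts summing to `n`.
#' @export
largest_remainder <- function(n, probs) {
  if (abs(sum(probs) - 1) > 1e-12) {
    abort_validation("proportions must sum to 1 (got %.15g)", sum(probs))
  }
  if (any(probs < 0)) abort_validation("proportions must be non-negative")
  quota <- n * probs
  counts <- floor(quota)
  leftover <- n - sum(counts)
  if (leftover > 0) {
    take <- order(-(quota - counts), seq_along(probs))[seq_len(leftover)]
    counts[take] <- counts[take] + 1
  }
  setNames(as.integer(counts), names(probs))
}

#' Distribution over rubric item triples from per-level weights
#'
#' Builds a categorical distribution over the 27 possible (obscenity,
#' impact, frequency) triples by giving each severity level a total
#' probability and spreading it uniformly over the triples the rubric
#' maps to that level. Useful for planting a target severity profile in
#' synthetic cohorts.
#'
#' @param level_probs Named numeric vector `c(moderate =, major =,
#'   severe =)` summing to 1; a level with zero probability may have no
#'   triples selected.
#' @return A tibble `obscenity, impact, frequency, prob`.
#' @export
effects_distribution_from_levels <- function(level_probs) {
  stopifnot(all(sort(names(level_probs)) == sort(EFFECT_LEVELS)))
  if (abs(sum(level_probs) - 1) > 1e-12) {
    abort_validation("level probabilities must sum to 1")
  }
  grid <- expand.grid(obscenity = 1:3, impact = 1:3, frequency = 1:3)
  lev <- as.character(score_assessment(grid$obscenity, grid$impact,
                                       grid$frequency)$level)
  prob <- numeric(nrow(grid))
  for (l in EFFECT_LEVELS) {
    in_l <- lev == l
    if (level_probs[[l]] > 0) {
      if (!any(in_l)) abort_validation("no triples map to level '%s'", l)
      prob[in_l] <- level_probs[[l]] / sum(in_l)
    }
  }
  out <- tibble::as_tibble(grid)
  out$prob <- prob
  out[out$prob > 0, ]
}

default_effects_distribution <- function() {
  # per-item independent probabilities (0.5, 0.3, 0.2) over moderate/major/severe
  p <- c(0.5, 0.3, 0.2)
  grid <- expand.grid(obscenity = 1:3, impact = 1:3, frequency = 1:3)
  out <- tibble::as_tibble(grid)
  out$prob <- p[grid$obscenity] * p[grid$impact] * p[grid$frequency]
  list(victim = out, bully_victim = out)
}

#' Configuration for a synthetic classroom cohort
#'
#' Defines the study conditions a generated cohort emulates: size,
#' demographics, planted role prevalences, nomination intensity and the
#' per-role severity profile of effects assessments.
#'
#' @param n_learners Cohort size (>= 4 when all four prevalences are
#'   positive).
#' @param grade_label Grade label, e.g. `"10"`.
#' @param gender_split Proportion of female learners in \[0, 1\].
#' @param age_mean,age_sd Age distribution in years; sampled ages are
#'   rounded to integers and truncated to the 10--30 plausibility band.
#' @param role_prevalence Proportions `c(bully =, bully_victim =,
#'   victim =, uninvolved =)` summing to 1.
#' @param mean_out_nominations Mean peer nominations emitted per
#'   victim-side learner (reporting intensity); default 1.5.
#' @param self_nomination_rate Probability a planted bully confesses via a
#'   self-nomination (receipt of a peer nomination is guaranteed as
#'   fallback); default 0.5.
#' @param effects_distribution Named list (`victim`, `bully_victim`) of
#'   triple distributions (tibbles `obscenity,impact,frequency,prob`);
#'   default: items drawn independently with probabilities (0.5, 0.3, 0.2).
#' @param seed Integer seed; the generator is fully deterministic given
#'   the configuration and seed.
#' @param rule_consistent Generate nominations consistent with the
#'   planted roles (default `TRUE`, guaranteeing exact role recovery);
#'   `FALSE` produces an adversarial cohort with random nominations whose
#'   classified roles may differ from the planted labels.
#' @return Object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_learners, grade_label = "10",
                          gender_split = 0.5,
                          age_mean = 16, age_sd = 1,
                          role_prevalence = c(bully = 0.2, bully_victim = 0.3,
                                              victim = 0.2, uninvolved = 0.3),
                          mean_out_nominations = 1.5,
                          self_nomination_rate = 0.5,
                          effects_distribution = NULL,
                          seed = 1L,
                          rule_consistent = TRUE) {
  stopifnot(n_learners >= 1)
  role_prevalence <- role_prevalence[ROLES]
  if (anyNA(role_prevalence)) {
    abort_validation("role_prevalence must name all of: %s",
                     paste(ROLES, collapse = ", "))
  }
  if (abs(sum(role_prevalence) - 1) > 1e-12) {
    abort_validation("role_prevalence must sum to 1")
  }
  for (r in c(gender_split, self_nomination_rate)) {
    if (r < 0 || r > 1) abort_validation("rates must lie in [0, 1]")
  }
  if (mean_out_nominations <= 0) {
    abort_validation("mean_out_nominations must be positive")
  }
  if (is.null(effects_distribution)) {
    effects_distribution <- default_effects_distribution()
  }
  structure(list(n_learners = as.integer(n_learners),
                 grade_label = as.character(grade_label),
                 gender_split = gender_split,
                 age_mean = age_mean, age_sd = age_sd,
                 role_prevalence = role_prevalence,
                 mean_out_nominations = mean_out_nominations,
                 self_nomination_rate = self_nomination_rate,
                 effects_distribution = effects_distribution,
                 seed = as.integer(seed),
                 rule_consistent = isTRUE(rule_consistent)),
            class = "cohort_config")
}

#' Preset cohort configurations
#'
#' Two canonical class-group presets matching the published role
#' prevalences and demographics of a grade-10 (N = 52) and a grade-12
#' (N = 27) cohort, with per-role effects-severity profiles matching the
#' published effects tables.
#'
#' @param name `"table5_grade10"` or `"table5_grade12"`.
#' @param seed Integer seed; default 1.
#' @return A `"cohort_config"`.
#' @export
preset_cohort_config <- function(name = c("table5_grade10", "table5_grade12"),
                                 seed = 1L) {
  name <- match.arg(name)
  if (name == "table5_grade10") {
    cohort_config(
      n_learners = 52, grade_label = "10", gender_split = 35 / 52,
      age_mean = 16.69, age_sd = 1.00,
      role_prevalence = c(bully = 0.21, bully_victim = 0.33,
                          victim = 0.19, uninvolved = 0.27),
      effects_distribution = list(
        bully_victim = effects_distribution_from_levels(
          c(moderate = 9 / 17, major = 0, severe = 8 / 17)),
        victim = effects_distribution_from_levels(
          c(moderate = 0.5, major = 0, severe = 0.5))),
      seed = seed)
  } else {
    cohort_config(
      n_learners = 27, grade_label = "12", gender_split = 15 / 27,
      age_mean = 19.30, age_sd = 1.48,
      role_prevalence = c(bully = 0.19, bully_victim = 0.52,
                          victim = 0.11, uninvolved = 0.18),
      effects_distribution = list(
        bully_victim = effects_distribution_from_levels(
          c(moderate = 8 / 14, major = 6 / 14, severe = 0)),
        victim = effects_distribution_from_levels(
          c(moderate = 0, major = 1, severe = 0))),
      seed = seed)
  }
}

sample_triples <- function(dist, k) {
  idx <- sample.int(nrow(dist), k, replace = TRUE, prob = dist$prob)
  dist[idx, c("obscenity", "impact", "frequency")]
}

#' Generate a synthetic classroom cohort
#'
#' Produces a roster, nominations and effects assessments. In
#' rule-consistent mode (the default) nominations are constructed so that
#' the role classifier recovers the planted roles exactly: every planted
#' victim and bully-victim emits at least one peer nomination targeting a
#' planted bully or bully-victim; every planted bully either confesses
#' (self-nomination, with probability `self_nomination_rate`) or is
#' guaranteed receipt of a peer nomination; planted uninvolved learners
#' neither emit nor receive nominations. Additional peer nominations are
#' added to reach the configured reporting intensity. Assessments are
#' drawn from the per-role effects distribution for victim-role holders.
#' Fully deterministic given the configuration (which includes the seed).
#'
#' @param config A `"cohort_config"`.
#' @return A `"cohort"` with attribute `"planted_roles"` (tibble
#'   `learner_id, role`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_learners
  counts <- largest_remainder(n, config$role_prevalence)

  # feasibility before any sampling
  n_bullyside <- counts[["bully"]] + counts[["bully_victim"]]
  n_victimside <- counts[["victim"]] + counts[["bully_victim"]]
  if (config$rule_consistent) {
    if (counts[["victim"]] > 0 && n_bullyside == 0) {
      abort_validation("infeasible config: victims planted but no bullies or bully-victims to nominate")
    }
    if (counts[["bully_victim"]] > 0 && n_bullyside < 2 && counts[["bully"]] == 0) {
      abort_validation("infeasible config: a lone bully-victim has no valid nomination target")
    }
    if (counts[["bully"]] > 0 && n_victimside == 0 && counts[["bully"]] < 2) {
      abort_validation("infeasible config: a planted bully can neither be nominated nor confess to anyone")
    }
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  ids <- sprintf("G%s-L%03d", config$grade_label, seq_len(n))
  n_female <- largest_remainder(n, c(female = config$gender_split,
                                     male = 1 - config$gender_split))[["female"]]
  gender <- sample(c(rep("female", n_female), rep("male", n - n_female)))
  age <- as.integer(pmin(pmax(round(stats::rnorm(n, config$age_mean,
                                                 config$age_sd)),
                              AGE_PLAUSIBLE[1]), AGE_PLAUSIBLE[2]))
  roster <- tibble::tibble(learner_id = ids, grade = config$grade_label,
                           gender = gender, age = age)

  role <- sample(rep(ROLES, counts))
  planted <- tibble::tibble(learner_id = ids, role = role)
  bullies <- ids[role == "bully"]
  bvs <- ids[role == "bully_victim"]
  victims <- ids[role == "victim"]
  bullyside <- c(bullies, bvs)
  victimside <- c(victims, bvs)

  noms <- list()
  add <- function(nominator, nominee, kind) {
    noms[[length(noms) + 1]] <<- c(nominator, nominee, kind)
  }

  if (config$rule_consistent) {
    # every victim-side learner names at least one bully-side peer
    peer_received <- character()
    for (v in victimside) {
      t <- sample(setdiff(bullyside, v), 1)
      add(v, t, "peer")
      peer_received <- c(peer_received, t)
    }
    # every bully-side learner must meet the bully criterion; each
    # confesses with the configured probability, and anyone who neither
    # confessed nor was already accused gets a guaranteed accusation
    for (b in sample(bullyside)) {
      accusers <- setdiff(victimside, b)
      confess <- stats::runif(1) < config$self_nomination_rate
      if (confess || (!(b %in% peer_received) && length(accusers) == 0)) {
        pool <- setdiff(victimside, b)
        if (length(pool) == 0) pool <- setdiff(bullyside, b)
        add(b, sample(pool, 1), "self")
      } else if (!(b %in% peer_received)) {
        add(sample(accusers, 1), b, "peer")
        peer_received <- c(peer_received, b)
      }
    }
    # extra peer nominations up to the reporting intensity
    extra_rate <- max(0, config$mean_out_nominations - 1)
    for (v in victimside) {
      k <- stats::rpois(1, extra_rate)
      if (k > 0) {
        pool <- setdiff(bullyside, v)
        k <- min(k, length(pool))
        for (t in sample(pool, k)) add(v, t, "peer")
      }
    }
  } else {
    # adversarial mode: random directed pairs, random kinds
    k <- stats::rpois(1, config$mean_out_nominations * n)
    if (k > 0 && n >= 2) {
      for (i in seq_len(k)) {
        pair <- sample(ids, 2)
        add(pair[1], pair[2], sample(NOMINATION_KINDS, 1))
      }
    }
  }

  nominations <- if (length(noms) > 0) {
    m <- do.call(rbind, noms)
    nom <- tibble::tibble(nominator_id = m[, 1], nominee_id = m[, 2],
                          kind = m[, 3])
    nom[!duplicated(nom), ]
  } else {
    tibble::tibble(nominator_id = character(), nominee_id = character(),
                   kind = character())
  }

  assessed <- planted$learner_id[planted$role %in% c("victim", "bully_victim")]
  assessments <- if (length(assessed) > 0) {
    rows <- lapply(assessed, function(id) {
      r <- planted$role[planted$learner_id == id]
      sample_triples(config$effects_distribution[[r]], 1)
    })
    tibble::tibble(learner_id = assessed, dplyr::bind_rows(rows))
  } else {
    tibble::tibble(learner_id = character(), obscenity = integer(),
                   impact = integer(), frequency = integer())
  }

  out <- cohort(roster, nominations, assessments)
  attr(out, "planted_roles") <- planted
  attr(out, "config") <- config
  out
}

#' Planted-versus-classified role recovery check
#'
#' Generates a cohort, classifies roles from its nominations, and compares
#' against the planted labels. In rule-consistent mode the construction
#' guarantees a perfect match; in adversarial mode the confusion matrix
#' quantifies the disagreement.
#'
#' @param config A `"cohort_config"`.
#' @param bully_victim_rule Passed to [classify_roles()].
#' @return List with `match_fraction` and `confusion` (matrix planted x
#'   classified).
#' @export
recovery_check <- function(config, bully_victim_rule = "and") {
  ch <- generate_cohort(config)
  planted <- attr(ch, "planted_roles")
  classified <- classify_roles(ch, bully_victim_rule = bully_victim_rule)
  cl <- classified$assignments
  cl <- cl[match(planted$learner_id, cl$learner_id), ]
  confusion <- table(planted = factor(planted$role, levels = ROLES),
                     classified = factor(cl$role, levels = ROLES))
  list(match_fraction = mean(planted$role == as.character(cl$role)),
       confusion = unclass(confusion))
}

#' Write a cohort's three tables to CSV files
#'
#' Writes `roster.csv`, `nominations.csv` and `assessments.csv` into a
#' directory; byte-stable for a given cohort.
#'
#' @param x A `"cohort"`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(roster = file.path(dir, "roster.csv"),
             nominations = file.path(dir, "nominations.csv"),
             assessments = file.path(dir, "assessments.csv"))
  readr::write_csv(x$learners, paths[["roster"]])
  readr::write_csv(x$nominations, paths[["nominations"]])
  readr::write_csv(x$assessments, paths[["assessments"]])
  invisible(paths)
}
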