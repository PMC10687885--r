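#' Configuration for the synthetic transitional-care cohort generator
#'
#' Builds a validated configuration for [generate_cohort()]. Defaults
#' emulate the marginal structure of a transitional hospital-to-home care
#' population: episode lengths from a truncated normal (mean 99.49 days,
#' SD 35.90, range 3-622); a 7-category case mix concentrated in
#' Clinically complex (41.6%) and Reduced physical functions (37.8%);
#' nine provider disciplines with PSW-dominated paid hours (about 74 paid
#' hours per episode overall); and heavily right-skewed unpaid caregiving
#' self-reports of about 10.6 hours per 3 days (roughly 350 hours over a
#' 99-day episode), correlated 0.8 between admission and discharge. A
#' quarter of episodes lack billing records.
#'
#' @param n_episodes Number of care episodes.
#' @param n_programs Number of transitional care programs episodes are
#'   spread over.
#' @param episode_length_days List with `mean`, `sd`, `min`, `max` of the
#'   truncated-normal episode length distribution (days).
#' @param category_mix Probability vector over the 7 categories in
#'   hierarchy order (must sum to 1).
#' @param within_category_group_mix Named list of probability vectors, one
#'   per category, over that category's groups in within-category rank
#'   order.
#' @param discipline_hour_model Data frame with columns `discipline`,
#'   `p_use` (probability an episode uses the discipline at all), `mean`
#'   and `sd` of unconditional paid hours per episode.
#' @param unpaid_3day_model List with `mean`, `sd` (hours per 3 days) and
#'   `corr` (admission-discharge correlation, on the log scale of the
#'   lognormal pair).
#' @param group_effect_multipliers Named numeric vector (23 groups):
#'   multiplicative effect of group membership on expected paid and unpaid
#'   care hours.
#' @param program_effect_multipliers Numeric vector (length `n_programs`):
#'   multiplicative program-level effect on expected paid hours.
#' @param missing_billing_rate Fraction of episodes whose billing records
#'   are removed.
#' @param missing_discharge_rate Fraction of episodes whose discharge
#'   unpaid-care report is removed.
#' @param seed Integer RNG seed; identical (config, seed) pairs generate
#'   identical cohorts.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_episodes = 1680,
                          n_programs = 8,
                          episode_length_days = list(mean = 99.49, sd = 35.90,
                                                     min = 3, max = 622),
                          category_mix = c(Rehabilitation = 0.104,
                                           ExtensiveServices = 0.003,
                                           SpecialCare = 0.058,
                                           ClinicallyComplex = 0.416,
                                           ImpairedCognition = 0.020,
                                           BehaviourProblems = 0.021,
                                           ReducedPhysicalFunctions = 0.378),
                          within_category_group_mix = default_group_mix(),
                          discipline_hour_model = default_discipline_model(),
                          unpaid_3day_model = list(mean = 10.6, sd = 17.0,
                                                   corr = 0.8),
                          group_effect_multipliers = default_group_effects(),
                          program_effect_multipliers = rep(1, n_programs),
                          missing_billing_rate = 0.25,
                          missing_discharge_rate = 0.10,
                          seed = 1L) {
  config <- list(
    n_episodes = n_episodes, n_programs = n_programs,
    episode_length_days = episode_length_days,
    category_mix = category_mix,
    within_category_group_mix = within_category_group_mix,
    discipline_hour_model = discipline_hour_model,
    unpaid_3day_model = unpaid_3day_model,
    group_effect_multipliers = group_effect_multipliers,
    program_effect_multipliers = program_effect_multipliers,
    missing_billing_rate = missing_billing_rate,
    missing_discharge_rate = missing_discharge_rate,
    seed = as.integer(seed)
  )
  class(config) <- "cohort_config"
  validate_cohort_config(config)
}

#' @rdname cohort_config
#' @export
#' @examples
#' default_group_mix()
default_group_mix <- function() {
  # within-category shares patterned on a transitional care population:
  # the lower-ranked groups (low ADL dependency) dominate
  list(
    Rehabilitation = c(RB = 0.10, RA2 = 0.20, RA1 = 0.70),
    ExtensiveServices = c(SE3 = 0.0, SE2 = 1.0, SE1 = 0.0),
    SpecialCare = c(SSB = 0.05, SSA = 0.95),
    ClinicallyComplex = c(CC = 0.06, CB = 0.13, CA2 = 0.48, CA1 = 0.33),
    ImpairedCognition = c(IB = 0.30, IA2 = 0.70, IA1 = 0.0),
    BehaviourProblems = c(BB = 0.17, BA2 = 0.53, BA1 = 0.30),
    ReducedPhysicalFunctions = c(PD = 0.07, PC = 0.03, PB = 0.09,
                                 PA2 = 0.43, PA1 = 0.38)
  )
}

#' @rdname cohort_config
#' @export
default_discipline_model <- function() {
  tibble::tibble(
    discipline = rug_disciplines(),
    p_use = c(0.90, 0.85, 0.65, 0.70, 0.10, 0.45, 0.35, 0.60, 0.95),
    mean  = c(13.96, 12.84, 4.63, 5.50, 0.97, 3.59, 1.93, 9.06, 41.34),
    sd    = c(12.51, 13.59, 5.09, 5.35, 3.21, 5.73, 2.89, 9.60, 52.47)
  )
}

#' @rdname cohort_config
#' @export
default_group_effects <- function() {
  # expected care hours fall with within-category rank: a mild gradient so
  # case-mix indices have structure to recover
  grp <- rug_groups()
  mult <- 1.6 * 0.8^(grp$within_category_rank - 1)
  stats::setNames(round(mult, 3), grp$code)
}

#' @rdname cohort_config
#' @param config A `cohort_config` list.
#' @export
validate_cohort_config <- function(config) {
  chk_prob_vec <- function(p, field) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop_config("%s must be a probability vector summing to 1", field)
    }
  }
  if (length(config$n_episodes) != 1 || config$n_episodes < 0 ||
      config$n_episodes != round(config$n_episodes)) {
    stop_config("n_episodes must be a non-negative integer")
  }
  if (config$n_programs < 1) stop_config("n_programs must be positive")
  len <- config$episode_length_days
  if (any(unlist(len) < 0) || len$min > len$max) {
    stop_config("episode_length_days requires non-negative mean/sd and min <= max")
  }
  cats <- rug_categories()$category
  if (!identical(names(config$category_mix), cats)) {
    stop_config("category_mix must be named by the 7 categories in hierarchy order")
  }
  chk_prob_vec(config$category_mix, "category_mix")
  grp <- rug_groups()
  for (cat in cats) {
    mix <- config$within_category_group_mix[[cat]]
    if (is.null(mix) ||
        !identical(names(mix), grp$code[grp$category == cat])) {
      stop_config("within_category_group_mix[%s] must cover that category's groups in rank order", cat)
    }
    chk_prob_vec(mix, sprintf("within_category_group_mix[%s]", cat))
  }
  dm <- config$discipline_hour_model
  if (!all(rug_disciplines() %in% dm$discipline)) {
    stop_config("discipline_hour_model must cover all nine disciplines")
  }
  if (any(dm$p_use < 0 | dm$p_use > 1)) {
    stop_config("discipline_hour_model p_use must lie in [0, 1]")
  }
  if (any(dm$mean < 0) || any(dm$sd < 0)) {
    stop_config("discipline_hour_model hours must be non-negative")
  }
  up <- config$unpaid_3day_model
  if (up$mean < 0 || up$sd < 0 || abs(up$corr) > 1) {
    stop_config("unpaid_3day_model requires non-negative mean/sd and corr in [-1, 1]")
  }
  if (!identical(sort(names(config$group_effect_multipliers)),
                 sort(grp$code)) ||
      any(config$group_effect_multipliers <= 0)) {
    stop_config("group_effect_multipliers must be positive and named by the 23 groups")
  }
  if (length(config$program_effect_multipliers) != config$n_programs ||
      any(config$program_effect_multipliers <= 0)) {
    stop_config("program_effect_multipliers must be %d positive values",
                config$n_programs)
  }
  for (field in c("missing_billing_rate", "missing_discharge_rate")) {
    r <- config[[field]]
    if (r < 0 || r > 1) stop_config("%s must lie in [0, 1]", field)
  }
  class(config) <- "cohort_config"
  invisible(config)
}

# inverse-CDF sampler for the truncated normal episode length
rtruncnorm_days <- function(n, mean, sd, min, max) {
  lo <- stats::pnorm(min, mean, sd)
  hi <- stats::pnorm(max, mean, sd)
  u <- stats::runif(n, lo, hi)
  pmin(pmax(round(stats::qnorm(u, mean, sd)), min), max)
}

# lognormal draws with prescribed (unconditional) mean and sd
rlnorm_meansd <- function(n, mean, sd, mult = 1) {
  if (mean <= 0) return(rep(0, n))
  sigma2 <- log(1 + (sd / mean)^2)
  mu <- log(mean * mult) - sigma2 / 2
  stats::rlnorm(n, meanlog = mu, sdlog = sqrt(sigma2))
}

# spread `extra` unit increments over `k` items with capacity `cap` each
compose_codes <- function(extra, k, cap) {
  slots <- sample(rep(seq_len(k), each = cap))
  tabulate(slots[seq_len(extra)], nbins = k)
}

#' Generate a synthetic transitional-care cohort
#'
#' Draws per-episode assessments and billing records with the statistical
#' structure the case-mix analysis assumes. Each episode is first assigned
#' a target RUG-III/HC group (category from `category_mix`, group from the
#' within-category mix); the generator then plants exactly the assessment
#' items that trigger that group under the supplied rule configuration —
#' the target category's trigger, no higher-ranked trigger, and ADL/IADL
#' codes drawn inside the band the group's split requires — so the grouper
#' reproduces the sampled group. Expected paid and unpaid care hours scale
#' with `group_effect_multipliers` (and paid hours additionally with
#' `program_effect_multipliers`), giving known relative resource weights
#' for parameter-recovery checks. Billing and discharge-report missingness
#' are then injected at the configured rates.
#'
#' @param config A [cohort_config()].
#' @param rules A rule configuration; defaults to [default_rule_config()].
#' @return A list with elements `assessments` (one row per episode; the
#'   sampled target group is carried in the `target_group` column) and
#'   `billing` (long: `episode_id`, `discipline`, `hours`).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_episodes = 50, seed = 7))
#' head(cohort$assessments)
#' head(cohort$billing)
generate_cohort <- function(config, rules = default_rule_config()) {
  validate_cohort_config(config)
  validate_rule_config(rules)
  n <- config$n_episodes
  grp <- rug_groups()
  if (n == 0) {
    return(list(assessments = empty_assessments(rules),
                billing = tibble::tibble(episode_id = character(0),
                                         discipline = character(0),
                                         hours = numeric(0))))
  }
  set.seed(config$seed)

  cats <- rug_categories()$category
  category <- sample(cats, n, replace = TRUE, prob = config$category_mix)
  group <- character(n)
  for (cat in cats) {
    idx <- which(category == cat)
    if (length(idx) == 0) next
    mix <- config$within_category_group_mix[[cat]]
    group[idx] <- sample(names(mix), length(idx), replace = TRUE, prob = mix)
  }

  episode_id <- sprintf("E%05d", seq_len(n))
  client_id <- sprintf("C%05d", seq_len(n))
  program_id <- sprintf("P%02d", sample.int(config$n_programs, n, replace = TRUE))
  len <- config$episode_length_days
  days <- rtruncnorm_days(n, len$mean, len$sd, len$min, len$max)
  episode_start <- as.Date("2019-01-01") + sample.int(1095, n, replace = TRUE)
  episode_end <- episode_start + days

  # --- plant assessment items that classify into the target group -------
  adl_items <- rules$adl_scale$items
  k_adl <- length(adl_items)
  code_lo <- rules$adl_scale$code_range[1]
  code_hi <- rules$adl_scale$code_range[2]
  cuts <- rules$adl_scale$band_cuts
  base <- k_adl * code_lo
  band_range <- list(A = c(base, cuts["A"]),
                     B = c(cuts["A"] + 1, cuts["B"]),
                     C = c(cuts["B"] + 1, cuts["C"]),
                     D = c(cuts["C"] + 1, k_adl * code_hi))

  target_band <- target_adl_bands(group, grp)
  target_iadl <- target_iadl_bands(group)

  adl_mat <- matrix(code_lo, n, k_adl,
                    dimnames = list(NULL, adl_items))
  score_target <- vapply(target_band, function(b) {
    r <- band_range[[b]]
    if (r[2] > r[1]) sample(seq(r[1], r[2]), 1) else r[1]
  }, numeric(1))
  for (i in seq_len(n)) {
    adl_mat[i, ] <- code_lo +
      compose_codes(score_target[i] - base, k_adl, code_hi - code_lo)
  }

  iadl_items <- rules$iadl_scale$items
  k_iadl <- length(iadl_items)
  i_lo <- rules$iadl_scale$code_range[1]
  i_hi <- rules$iadl_scale$code_range[2]
  cut <- rules$iadl_scale$difficulty_cut
  iadl_mat <- matrix(i_lo, n, k_iadl, dimnames = list(NULL, iadl_items))
  some <- which(target_iadl == "some")
  if (length(some) > 0) {
    draw <- matrix(sample(seq(i_lo, i_hi), length(some) * k_iadl,
                          replace = TRUE, prob = c(0.5, rep(0.5 / (i_hi - i_lo), i_hi - i_lo))),
                   nrow = length(some))
    # guarantee at least one item at/above the cut
    none_yet <- rowSums(draw >= cut) == 0
    if (any(none_yet)) {
      j <- sample.int(k_iadl, sum(none_yet), replace = TRUE)
      draw[cbind(which(none_yet), j)] <-
        sample(seq(cut, i_hi), sum(none_yet), replace = TRUE)
    }
    iadl_mat[some, ] <- draw
  }

  # triggers: only the target category's own trigger is planted, so no
  # higher-ranked category can pre-empt it
  therapy <- stats::runif(n, 0, rules$category_triggers$Rehabilitation$min_minutes_7day - 1)
  therapy[category == "Rehabilitation"] <-
    stats::runif(sum(category == "Rehabilitation"),
                 rules$category_triggers$Rehabilitation$min_minutes_7day, 600)
  cognition <- sample(0:2, n, replace = TRUE)
  icog <- category == "ImpairedCognition"
  cognition[icog] <- sample(rules$category_triggers$ImpairedCognition$min_score:6,
                            sum(icog), replace = TRUE)

  clin_flags <- unique(c(rules$category_triggers$ExtensiveServices$flags,
                         rules$category_triggers$SpecialCare$flags,
                         rules$category_triggers$ClinicallyComplex$flags))
  clin <- matrix(0L, n, length(clin_flags),
                 dimnames = list(NULL, paste0("clin_", clin_flags)))
  ext_idx <- which(category == "ExtensiveServices")
  for (i in ext_idx) {
    k <- c(SE3 = 3, SE2 = 2, SE1 = 1)[group[i]]
    chosen <- sample(rules$category_triggers$ExtensiveServices$flags, k)
    clin[i, paste0("clin_", chosen)] <- 1L
  }
  for (i in which(category == "SpecialCare")) {
    chosen <- sample(rules$category_triggers$SpecialCare$flags, 1)
    clin[i, paste0("clin_", chosen)] <- 1L
  }
  for (i in which(category == "ClinicallyComplex")) {
    pool <- rules$category_triggers$ClinicallyComplex$flags
    chosen <- sample(pool, sample(1:2, 1))
    clin[i, paste0("clin_", chosen)] <- 1L
  }

  beh_flags <- rules$category_triggers$BehaviourProblems$flags
  beh <- matrix(0L, n, length(beh_flags),
                dimnames = list(NULL, paste0("beh_", beh_flags)))
  for (i in which(category == "BehaviourProblems")) {
    chosen <- sample(beh_flags, 1)
    beh[i, paste0("beh_", chosen)] <- 1L
  }

  # --- unpaid caregiving: correlated lognormal admission/discharge pair --
  up <- config$unpaid_3day_model
  mult <- config$group_effect_multipliers[group]
  if (up$mean > 0) {
    sigma2 <- log(1 + (up$sd / up$mean)^2)
    mu <- log(up$mean * mult) - sigma2 / 2
    z1 <- stats::rnorm(n)
    z2 <- up$corr * z1 + sqrt(1 - up$corr^2) * stats::rnorm(n)
    unpaid_adm <- exp(mu + sqrt(sigma2) * z1)
    unpaid_dis <- exp(mu + sqrt(sigma2) * z2)
  } else {
    unpaid_adm <- unpaid_dis <- rep(0, n)
  }

  age <- pmin(pmax(round(stats::rnorm(n, 76.35, 12.94)), 17), 110)
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.593, 0.407))

  assessments <- tibble::tibble(
    episode_id = episode_id, client_id = client_id, program_id = program_id,
    episode_start = episode_start, episode_end = episode_end,
    age = age, sex = sex,
    therapy_minutes_7day = round(therapy, 1),
    cognitive_performance = cognition,
    unpaid_hours_3day_admission = round(unpaid_adm, 2),
    unpaid_hours_3day_discharge = round(unpaid_dis, 2),
    target_group = group
  )
  assessments <- dplyr::bind_cols(assessments,
                                  tibble::as_tibble(adl_mat),
                                  tibble::as_tibble(iadl_mat),
                                  tibble::as_tibble(clin),
                                  tibble::as_tibble(beh))

  # --- billing: per-discipline use and lognormal hours -------------------
  dm <- config$discipline_hour_model
  prog_mult <- config$program_effect_multipliers[as.integer(sub("^P", "", program_id))]
  billing_parts <- lapply(seq_len(nrow(dm)), function(j) {
    used <- stats::runif(n) < dm$p_use[j]
    if (!any(used)) return(NULL)
    idx <- which(used)
    # conditional-on-use mean so the unconditional mean is dm$mean * effect
    hours <- rlnorm_meansd(length(idx), dm$mean[j] / dm$p_use[j], dm$sd[j] / dm$p_use[j],
                           mult = mult[idx] * prog_mult[idx])
    tibble::tibble(episode_id = episode_id[idx],
                   discipline = dm$discipline[j],
                   hours = round(hours, 2))
  })
  billing <- dplyr::bind_rows(billing_parts)
  # every episode gets at least one record (a token PSW visit) before
  # missingness injection
  uncovered <- setdiff(episode_id, billing$episode_id)
  if (length(uncovered) > 0) {
    billing <- dplyr::bind_rows(billing, tibble::tibble(
      episode_id = uncovered, discipline = "PSW",
      hours = round(stats::runif(length(uncovered), 0.5, 2), 2)))
  }
  billing <- dplyr::arrange(billing, episode_id, discipline)

  inject_missingness(assessments, billing,
                     missing_billing_rate = config$missing_billing_rate,
                     missing_discharge_rate = config$missing_discharge_rate,
                     seed = config$seed + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ADL band each group's split requires; groups whose split spans several
# bands get one drawn uniformly (SE* splits ignore ADL entirely)
target_adl_bands <- function(group, grp) {
  pick <- function(bands) if (length(bands) == 1) bands else sample(bands, 1)
  vapply(group, function(g) {
    switch(g,
      RA1 = , RA2 = , SSA = , CA1 = , CA2 = , IA1 = , IA2 = ,
      BA1 = , BA2 = , PA1 = , PA2 = "A",
      PB = , CB = "B",
      PC = "C",
      PD = "D",
      CC = pick(c("C", "D")),
      RB = , SSB = , IB = , BB = pick(c("B", "C", "D")),
      SE3 = , SE2 = , SE1 = pick(c("A", "A", "B", "C"))
    )
  }, character(1))
}

target_iadl_bands <- function(group) {
  vapply(group, function(g) {
    if (g %in% c("RA1", "CA1", "IA1", "BA1", "PA1")) "none"
    else if (g %in% c("RA2", "CA2", "IA2", "BA2", "PA2")) "some"
    else sample(c("none", "some"), 1, prob = c(0.3, 0.7))
  }, character(1))
}

empty_assessments <- function(rules) {
  clin_flags <- unique(c(rules$category_triggers$ExtensiveServices$flags,
                         rules$category_triggers$SpecialCare$flags,
                         rules$category_triggers$ClinicallyComplex$flags))
  beh_flags <- rules$category_triggers$BehaviourProblems$flags
  out <- tibble::tibble(
    episode_id = character(0), client_id = character(0),
    program_id = character(0),
    episode_start = as.Date(character(0)), episode_end = as.Date(character(0)),
    age = numeric(0), sex = character(0),
    therapy_minutes_7day = numeric(0), cognitive_performance = integer(0),
    unpaid_hours_3day_admission = numeric(0),
    unpaid_hours_3day_discharge = numeric(0),
    target_group = character(0)
  )
  for (nm in c(rules$adl_scale$items, rules$iadl_scale$items,
               paste0("clin_", clin_flags), paste0("beh_", beh_flags))) {
    out[[nm]] <- integer(0)
  }
  out
}

#' Inject billing and discharge-report missingness
#'
#' Removes all billing records for a seeded random fraction of episodes
#' (emulating incomplete administrative billing extracts) and blanks the
#' discharge unpaid-care self-report for another fraction. Admission
#' assessment data are never removed.
#'
#' @param assessments,billing Cohort tables as returned by
#'   [generate_cohort()].
#' @param missing_billing_rate,missing_discharge_rate Fractions in
#'   \[0, 1\].
#' @param seed Integer seed controlling which episodes are affected.
#' @return A list with the modified `assessments` and `billing`.
#' @export
inject_missingness <- function(assessments, billing,
                               missing_billing_rate = 0,
                               missing_discharge_rate = 0,
                               seed = 1L) {
  for (r in c(missing_billing_rate, missing_discharge_rate)) {
    if (is.na(r) || r < 0 || r > 1) {
      stop_config("missingness rates must lie in [0, 1]")
    }
  }
  if (missing_billing_rate == 0 && missing_discharge_rate == 0) {
    return(list(assessments = assessments, billing = billing))
  }
  set.seed(seed)
  ids <- assessments$episode_id
  n <- length(ids)
  drop_billing <- ids[stats::runif(n) < missing_billing_rate]
  drop_discharge <- ids[stats::runif(n) < missing_discharge_rate]
  billing <- billing[!(billing$episode_id %in% drop_billing), , drop = FALSE]
  assessments$unpaid_hours_3day_discharge[
    assessments$episode_id %in% drop_discharge] <- NA_real_
  list(assessments = assessments, billing = billing)
}
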