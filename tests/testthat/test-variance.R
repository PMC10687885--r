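test_that("r_squared matches exact fits and rejects degenerate designs", {
  expect_equal(
    suppressWarnings(r_squared(c(1, 2, 3, 4), data.frame(x = c(1, 2, 3, 4)))),
    1)
  set.seed(3)
  y <- rnorm(20)
  expect_error(r_squared(y, data.frame(x = rep(2, 20))),
               class = "rughc_model_error")
  expect_error(r_squared(rep(1, 10), data.frame(x = 1:10)),
               class = "rughc_model_error")
  # collinear columns are a rank-deficiency error, not a silent drop
  x <- rnorm(20)
  expect_error(r_squared(y, data.frame(a = x, b = 2 * x)),
               class = "rughc_model_error")
})

test_that("cmi_only R-squared equals the between-group variance share", {
  # brute-force decomposition oracle on a 3-group, 30-episode set
  set.seed(17)
  groups3 <- rep(c("CA1", "CB", "PA1"), each = 10)
  y <- c(rnorm(10, 10, 2), rnorm(10, 20, 3), rnorm(10, 35, 4))
  measures <- tibble::tibble(
    episode_id = sprintf("E%d", 1:30), episode_days = 10L,
    paid_hours = y, paid_cost = y, unpaid_hours = 0,
    total_hours = y, total_cost = y)
  groups <- tibble::tibble(episode_id = measures$episode_id, group = groups3)
  tab <- case_mix_table(measures, groups)
  aug <- attach_cmi(measures, groups, tab)
  r2 <- r_squared(aug$paid_hours, data.frame(cmi = aug$cmi_paid_hours))

  grand <- mean(y)
  ss_total <- sum((y - grand)^2)
  ss_between <- sum(tapply(y, groups3, function(v) {
    length(v) * (mean(v) - grand)^2
  }))
  expect_equal(r2, ss_between / ss_total, tolerance = 1e-10)
})

test_that("attach_cmi looks up the group CMI and accounts for exclusions", {
  measures <- tibble::tibble(
    episode_id = c("E1", "E2"), episode_days = 10L,
    paid_hours = c(1, 3), paid_cost = c(1, 3), unpaid_hours = 0,
    total_hours = c(1, 3), total_cost = c(1, 3))
  groups <- tibble::tibble(episode_id = c("E1", "E2"),
                           group = c("CA1", "PA1"))
  tab <- case_mix_table(measures, groups)
  aug <- attach_cmi(measures, groups, tab)
  expect_equal(aug$cmi_paid_hours, c(0.5, 1.5))
  expect_identical(attr(aug, "n_excluded"), 0L)

  # an episode whose group has an NA CMI in the supplied table is excluded
  extra_m <- dplyr::bind_rows(measures, tibble::tibble(
    episode_id = "E3", episode_days = 10L, paid_hours = 9, paid_cost = 9,
    unpaid_hours = 0, total_hours = 9, total_cost = 9))
  extra_g <- dplyr::bind_rows(groups,
                              tibble::tibble(episode_id = "E3", group = "SE2"))
  aug2 <- attach_cmi(extra_m, extra_g, tab)  # tab has no SE2 episodes
  expect_identical(nrow(aug2), 2L)
  expect_identical(attr(aug2, "n_excluded"), 1L)
})

test_that("outcome deterministic in the CMI gives R-squared 1 everywhere", {
  set.seed(29)
  groups3 <- sample(c("CC", "CB", "CA1"), 60, replace = TRUE)
  base <- c(CC = 40, CB = 25, CA1 = 10)[groups3]
  measures <- tibble::tibble(
    episode_id = sprintf("E%d", 1:60), episode_days = 10L,
    paid_hours = base, paid_cost = base, unpaid_hours = 0,
    total_hours = base, total_cost = base)
  groups <- tibble::tibble(episode_id = measures$episode_id, group = groups3)
  programs <- tibble::tibble(episode_id = measures$episode_id,
                             program_id = "P01")
  # lm warns about the exact fit; the exactness is the point here
  ev <- suppressWarnings(evaluation_table(measures, measures, groups, programs))
  expect_identical(nrow(ev), 16L)
  expect_equal(ev$r_squared, rep(1, 16), tolerance = 1e-10)
})

test_that("adding the program indicator never decreases R-squared", {
  for (seed in c(101, 202)) {
    cfg <- cohort_config(n_episodes = 400, seed = seed)
    cohort <- generate_cohort(cfg)
    groups <- classify_cohort(cohort$assessments, default_rule_config())
    measures <- episode_measures(cohort$assessments, cohort$billing)
    ev <- evaluation_table(measures, trim_operational(measures), groups,
                           cohort$assessments[, c("episode_id", "program_id")])
    wide <- merge(ev[ev$model == "cmi_only", c("measure", "sample", "r_squared")],
                  ev[ev$model == "cmi_plus_program",
                     c("measure", "sample", "r_squared")],
                  by = c("measure", "sample"), suffixes = c("_cmi", "_both"))
    expect_true(all(wide$r_squared_both >= wide$r_squared_cmi - 1e-10))
  }
})

test_that("program-level effects raise the program model's R-squared", {
  # three programs with multiplicative paid-hour effects 0.5 / 1 / 2:
  # the program indicator must add real explanatory power
  cfg <- cohort_config(n_episodes = 3000, seed = 55, n_programs = 3,
                       program_effect_multipliers = c(0.5, 1, 2),
                       missing_billing_rate = 0)
  cohort <- generate_cohort(cfg)
  groups <- classify_cohort(cohort$assessments, default_rule_config())
  measures <- episode_measures(cohort$assessments, cohort$billing)
  ev <- evaluation_table(measures, trim_operational(measures), groups,
                         cohort$assessments[, c("episode_id", "program_id")])
  paid <- ev[ev$measure == "paid_hours" & ev$sample == "full", ]
  gain <- paid$r_squared[paid$model == "cmi_plus_program"] -
    paid$r_squared[paid$model == "cmi_only"]
  expect_gt(gain, 0.02)

  # with no program effects the gain is within noise
  cfg0 <- cohort_config(n_episodes = 3000, seed = 55, n_programs = 3,
                        missing_billing_rate = 0)
  cohort0 <- generate_cohort(cfg0)
  groups0 <- classify_cohort(cohort0$assessments, default_rule_config())
  measures0 <- episode_measures(cohort0$assessments, cohort0$billing)
  ev0 <- evaluation_table(measures0, trim_operational(measures0), groups0,
                          cohort0$assessments[, c("episode_id", "program_id")])
  paid0 <- ev0[ev0$measure == "paid_hours" & ev0$sample == "full", ]
  gain0 <- paid0$r_squared[paid0$model == "cmi_plus_program"] -
    paid0$r_squared[paid0$model == "cmi_only"]
  expect_lt(gain0, 0.01)
  expect_gt(gain, gain0)
})
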