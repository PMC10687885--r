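test_that("cost weights standardize by the PSW rate", {
  equal <- standardize_weights(c(PSW = 40, RN = 40, OT = 40))
  expect_true(all(equal$weight == 1))

  w <- standardize_weights(c(PSW = 25, RN = 50))
  expect_identical(w$weight[["PSW"]], 1)
  expect_identical(w$weight[["RN"]], 2)
  expect_identical(w$unpaid_weight, 1.0)

  # ratio identity: rescaling all rates leaves the weights unchanged
  rates <- c(PSW = 33, RN = 71, RPN = 52, PT = 104)
  expect_equal(standardize_weights(rates)$weight,
               standardize_weights(rates * 7.3)$weight)

  expect_error(standardize_weights(c(RN = 50)), "PSW",
               class = "rughc_config_error")
  expect_error(standardize_weights(c(PSW = 25, RN = -1)),
               class = "rughc_config_error")
})

test_that("paid measures aggregate hours and weighted cost", {
  w <- standardize_weights(c(PSW = 25, RN = 50))
  expect_identical(
    paid_measures(data.frame(discipline = character(0), hours = numeric(0)), w),
    c(paid_hours = 0, paid_cost = 0))
  got <- paid_measures(data.frame(discipline = c("PSW", "RN"),
                                  hours = c(3, 4)), w)
  expect_equal(got, c(paid_hours = 7, paid_cost = 11))
  # identity weights collapse cost onto hours
  set.seed(2)
  billing <- data.frame(
    discipline = sample(c("PSW", "RN", "OT"), 30, replace = TRUE),
    hours = round(runif(30, 0, 10), 2))
  w1 <- standardize_weights(c(PSW = 40, RN = 40, OT = 40))
  got <- paid_measures(billing, w1)
  expect_equal(got[["paid_cost"]], got[["paid_hours"]])
  expect_error(paid_measures(data.frame(discipline = "MD", hours = 1), w),
               "MD", class = "rughc_data_error")
})

test_that("unpaid hours follow the 3-day-report convention", {
  expect_identical(estimate_unpaid_hours(0, 0, 50), 0)
  expect_equal(estimate_unpaid_hours(6, 12, 100), 300)
  expect_equal(estimate_unpaid_hours(9, NA, 30), 90)
  # vectorized with mixed discharge availability
  expect_equal(estimate_unpaid_hours(c(6, 9), c(12, NA), c(100, 30)),
               c(300, 90))
  expect_error(estimate_unpaid_hours(-1, 0, 10), class = "rughc_data_error")
  expect_error(estimate_unpaid_hours(1, 1, 0), class = "rughc_data_error")
})

test_that("operational trimming removes strict quantile outliers", {
  df <- data.frame(episode_days = 1:100)
  kept <- trim_operational(df, 0.01, 0.05)
  # brute force on the explicit 1..100 vector: type-7 quantiles are 1.99
  # and 95.05, so day 1 and days 96-100 fall strictly outside
  expect_identical(kept$episode_days, 2:95)
  expect_identical(attr(kept, "n_trimmed"), 6L)

  expect_identical(trim_operational(df, 0, 0)$episode_days, df$episode_days)
  allsame <- data.frame(episode_days = rep(30L, 40))
  expect_identical(nrow(trim_operational(allsame, 0.01, 0.05)), 40L)
  expect_error(trim_operational(df, 0.5, 0.5), class = "rughc_config_error")
})

test_that("retained size is non-increasing in either trim fraction", {
  set.seed(4)
  df <- data.frame(episode_days = sample(3:300, 150, replace = TRUE))
  sizes_low <- vapply(c(0, 0.01, 0.05, 0.1, 0.2),
                      function(p) nrow(trim_operational(df, p, 0.05)),
                      numeric(1))
  sizes_high <- vapply(c(0, 0.01, 0.05, 0.1, 0.2),
                       function(p) nrow(trim_operational(df, 0.01, p)),
                       numeric(1))
  expect_true(all(diff(sizes_low) <= 0))
  expect_true(all(diff(sizes_high) <= 0))
})

test_that("episode measures decompose into paid plus unpaid", {
  cfg <- cohort_config(n_episodes = 150, seed = 21)
  cohort <- generate_cohort(cfg)
  m <- episode_measures(cohort$assessments, cohort$billing)
  expect_equal(m$total_hours, m$paid_hours + m$unpaid_hours)
  expect_equal(m$total_cost,
               m$paid_cost + default_cost_weights()$unpaid_weight * m$unpaid_hours)
  expect_identical(nrow(m) + attr(m, "n_missing_billing"),
                   nrow(cohort$assessments))
  expect_true(all(m$paid_cost >= m$paid_hours))  # all weights >= 1 vs PSW
})

test_that("unpaid volume per episode is of the expected order", {
  cfg <- cohort_config(n_episodes = 800, seed = 31)
  cohort <- generate_cohort(cfg)
  m <- episode_measures(cohort$assessments, cohort$billing)
  # configured 10.6 h / 3 days over a ~99.5-day episode, times the mean
  # group effect: the observed mean must sit within wide sampling error
  mult <- cfg$group_effect_multipliers[cohort$assessments$target_group]
  expected <- cfg$unpaid_3day_model$mean / 3 *
    cfg$episode_length_days$mean * mean(mult)
  se <- sd(m$unpaid_hours) / sqrt(nrow(m))
  expect_lt(abs(mean(m$unpaid_hours) - expected), 4 * se + 0.1 * expected)
})
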