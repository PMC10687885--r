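config <- default_rule_config()

test_that("ADL score hits the floor and ceiling bands", {
  lo <- make_record(config, adl = config$adl_scale$code_range[1])
  hi <- make_record(config, adl = config$adl_scale$code_range[2])
  expect_identical(as.character(adl_score(lo, config)$band), "A")
  expect_equal(adl_score(lo, config)$score, 4)
  expect_identical(as.character(adl_score(hi, config)$band), "D")
  expect_equal(adl_score(hi, config)$score, 20)
})

test_that("ADL band is monotone over the full single-item code enumeration", {
  # brute force: every 4-item code vector in the code range, then every
  # one-item increment must keep the band non-decreasing
  rng <- seq(config$adl_scale$code_range[1], config$adl_scale$code_range[2])
  grid <- expand.grid(a = rng, b = rng, c = rng, d = rng)
  names(grid) <- config$adl_scale$items
  bands <- adl_score(grid, config)$band
  band_rank <- as.integer(bands)
  for (j in seq_along(config$adl_scale$items)) {
    can_bump <- grid[[j]] < max(rng)
    bumped <- grid[can_bump, , drop = FALSE]
    bumped[[j]] <- bumped[[j]] + 1
    expect_true(all(as.integer(adl_score(bumped, config)$band) >=
                      band_rank[can_bump]))
  }
})

test_that("ADL errors identify missing or invalid items", {
  rec <- make_record(config)
  rec$adl_transfer <- NULL
  expect_error(adl_score(rec, config), "adl_transfer",
               class = "rughc_classification_error")
  rec <- make_record(config)
  rec$adl_eating <- 9
  expect_error(adl_score(rec, config), "adl_eating",
               class = "rughc_classification_error")
  rec <- make_record(config)
  rec$adl_eating <- NA
  expect_error(adl_score(rec, config), class = "rughc_classification_error")
})

test_that("IADL band matches its definition on an exhaustive 2-item grid", {
  expect_identical(iadl_band(make_record(config, iadl = 0), config), "none")
  one_up <- make_record(config, iadl = 0)
  one_up$iadl_phone_use <- config$iadl_scale$difficulty_cut
  expect_identical(iadl_band(one_up, config), "some")

  # enumeration oracle over the first two items, remaining items at 0
  rng <- seq(config$iadl_scale$code_range[1], config$iadl_scale$code_range[2])
  for (c1 in rng) for (c2 in rng) {
    rec <- make_record(config, iadl = 0)
    rec$iadl_meal_preparation <- c1
    rec$iadl_housework <- c2
    expected <- if (any(c(c1, c2) >= config$iadl_scale$difficulty_cut)) {
      "some"
    } else {
      "none"
    }
    expect_identical(iadl_band(rec, config), expected)
  }
  rec <- make_record(config)
  rec$iadl_housework <- NULL
  expect_error(iadl_band(rec, config), class = "rughc_classification_error")
})

test_that("classification follows the hierarchy and the splits", {
  # no triggers, minimum ADL, no IADL difficulty: terminal default, lowest
  expect_identical(classify_episode(make_record(config), config)$group, "PA1")
  # clinically complex trigger, band-A ADL, some IADL difficulty
  rec <- make_record(config, adl = 1, iadl = c(2, 0, 0, 0, 0),
                     clin = "pneumonia")
  expect_identical(classify_episode(rec, config)$group,
                   oracle_classify(rec, config))
  expect_identical(classify_episode(rec, config)$group, "CA2")
  # rehabilitation precedence over a simultaneous clinically-complex trigger
  rec <- make_record(config, adl = 3, therapy = 150, clin = "pneumonia")
  expect_identical(classify_episode(rec, config)$category, "Rehabilitation")
  # extensive services split counts distinct services
  for (k in 1:3) {
    rec <- make_record(
      config, adl = 2,
      clin = config$category_triggers$ExtensiveServices$flags[seq_len(k)])
    expect_identical(classify_episode(rec, config)$group,
                     c("SE1", "SE2", "SE3")[k])
  }
})

test_that("adding a higher-ranked trigger never demotes the category", {
  rank_of <- function(cat) rug_categories()$rank[rug_categories()$category == cat]
  set.seed(11)
  boosters <- list(
    function(r) { r$therapy_minutes_7day <- 300; r },
    function(r) { r$clin_iv_medication <- 1L; r },
    function(r) { r$clin_tube_feeding <- 1L; r },
    function(r) { r$clin_pneumonia <- 1L; r },
    function(r) { r$cognitive_performance <- 5; r },
    function(r) { r$beh_wandering <- 1L; r }
  )
  for (i in 1:40) {
    rec <- make_record(
      config,
      adl = sample(1:5, 4, replace = TRUE),
      iadl = sample(0:3, 5, replace = TRUE),
      therapy = sample(c(0, 200), 1),
      cognition = sample(0:5, 1),
      clin = sample(all_clinical_flags(config),
                    sample(0:2, 1)),
      beh = sample(config$category_triggers$BehaviourProblems$flags,
                   sample(0:1, 1)))
    before <- rank_of(classify_episode(rec, config)$category)
    booster_rank <- sample(seq_along(boosters), 1)
    boosted <- boosters[[booster_rank]](rec)
    after <- rank_of(classify_episode(boosted, config)$category)
    # the new trigger set is the old one plus rank `booster_rank`, so the
    # first satisfied trigger is exactly the better of the two
    expect_identical(after, min(before, booster_rank))
    expect_lte(after, before)
  }
})

test_that("distribution_table reports counts, percentages and subtotals", {
  tab <- distribution_table(c("CA2", "CA2", "PA1"))
  expect_identical(tab$count[tab$label == "CA2"], 2L)
  expect_identical(tab$percent[tab$label == "CA2"], 66.7)
  expect_identical(tab$percent[tab$label == "ClinicallyComplex"], 66.7)
  expect_identical(tab$count[tab$label == "Total"], 3L)
  expect_identical(tab$percent[tab$label == "Total"], 100.0)
  # single episode: its group 100, every other group 0
  tab1 <- distribution_table("RB")
  expect_identical(tab1$percent[tab1$label == "RB"], 100.0)
  expect_true(all(tab1$percent[tab1$level == "group" & tab1$label != "RB"] == 0))
  # group counts always sum to input size
  expect_identical(sum(tab$count[tab$level == "group"]), 3L)
  # empty input: zero total, no NaN percentages
  tab0 <- distribution_table(character(0))
  expect_identical(tab0$count[tab0$label == "Total"], 0L)
  expect_false(anyNA(tab0$percent))
  expect_error(distribution_table("XX"), class = "rughc_data_error")
})
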