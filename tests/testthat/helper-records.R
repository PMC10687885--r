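# Shared fixture builders and independent oracles for the test suite.
# Everything is built in code at test time.

all_clinical_flags <- function(rules = default_rule_config()) {
  unique(c(rules$category_triggers$ExtensiveServices$flags,
           rules$category_triggers$SpecialCare$flags,
           rules$category_triggers$ClinicallyComplex$flags))
}

# One assessment record with every configured item column present.
# `adl` is a scalar code for all four items or a full code vector; `clin`
# and `beh` are flag-name character vectors to switch on.
make_record <- function(rules = default_rule_config(),
                        adl = 1, iadl = 0,
                        therapy = 0, cognition = 0,
                        clin = character(0), beh = character(0),
                        episode_id = "E1") {
  rec <- data.frame(episode_id = episode_id, stringsAsFactors = FALSE)
  adl_items <- rules$adl_scale$items
  if (length(adl) == 1) adl <- rep(adl, length(adl_items))
  for (i in seq_along(adl_items)) rec[[adl_items[i]]] <- adl[i]
  iadl_items <- rules$iadl_scale$items
  if (length(iadl) == 1) iadl <- rep(iadl, length(iadl_items))
  for (i in seq_along(iadl_items)) rec[[iadl_items[i]]] <- iadl[i]
  rec$therapy_minutes_7day <- therapy
  rec$cognitive_performance <- cognition
  for (f in all_clinical_flags(rules)) {
    rec[[paste0("clin_", f)]] <- as.integer(f %in% clin)
  }
  for (f in rules$category_triggers$BehaviourProblems$flags) {
    rec[[paste0("beh_", f)]] <- as.integer(f %in% beh)
  }
  rec
}

# Independent brute-force re-evaluation of the rule config for one record:
# scans triggers and split rules directly, with its own band arithmetic,
# sharing no code path with classify_episode().
oracle_classify <- function(record, rules = default_rule_config()) {
  clin_on <- all_clinical_flags(rules)
  clin_on <- clin_on[vapply(clin_on, function(f) {
    record[[paste0("clin_", f)]] == 1
  }, logical(1))]
  beh_on <- rules$category_triggers$BehaviourProblems$flags
  beh_on <- beh_on[vapply(beh_on, function(f) {
    record[[paste0("beh_", f)]] == 1
  }, logical(1))]

  trig <- function(cat) {
    t <- rules$category_triggers[[cat]]
    if (t$type == "always") return(TRUE)
    if (t$type == "therapy") {
      return(record$therapy_minutes_7day >= t$min_minutes_7day)
    }
    if (t$type == "cognition") {
      return(record$cognitive_performance >= t$min_score)
    }
    if (t$type == "clinical_any") return(any(t$flags %in% clin_on))
    if (t$type == "behaviour_any") return(any(t$flags %in% beh_on))
    stop("unknown trigger")
  }
  category <- NA
  for (cat in rug_categories()$category) {
    if (trig(cat)) { category <- cat; break }
  }

  score <- 0
  for (item in rules$adl_scale$items) {
    score <- score + rules$adl_scale$weights[[item]] * record[[item]]
  }
  cuts <- rules$adl_scale$band_cuts
  band <- if (score <= cuts[["A"]]) "A" else if (score <= cuts[["B"]]) "B" else if (score <= cuts[["C"]]) "C" else "D"

  some <- FALSE
  for (item in rules$iadl_scale$items) {
    if (record[[item]] >= rules$iadl_scale$difficulty_cut) some <- TRUE
  }
  iadl <- if (some) "some" else "none"

  n_serv <- sum(rules$category_triggers$ExtensiveServices$flags %in% clin_on)
  for (r in rules$split_map[[category]]) {
    ok <- TRUE
    if (!is.null(r$min_services) && n_serv < r$min_services) ok <- FALSE
    if (!is.null(r$adl_bands) && !(band %in% r$adl_bands)) ok <- FALSE
    if (!is.null(r$iadl) && r$iadl != iadl) ok <- FALSE
    if (ok) return(r$group)
  }
  NA_character_
}

# Full-sample and operational group counts of a transitional care
# population (used as worked-example inputs to the distribution table)
table2_full_counts <- c(
  RB = 17, RA2 = 34, RA1 = 123,
  SE3 = 0, SE2 = 5, SE1 = 0,
  SSB = 5, SSA = 92,
  CC = 41, CB = 89, CA2 = 338, CA1 = 231,
  IB = 10, IA2 = 24, IA1 = 0,
  BB = 6, BA2 = 19, BA1 = 11,
  PD = 46, PC = 21, PB = 59, PA2 = 270, PA1 = 239
)

table2_operational_counts <- c(
  RB = 17, RA2 = 34, RA1 = 113,
  SE3 = 0, SE2 = 4, SE1 = 0,
  SSB = 4, SSA = 87,
  CC = 37, CB = 85, CA2 = 317, CA1 = 212,
  IB = 9, IA2 = 24, IA1 = 0,
  BB = 6, BA2 = 17, BA1 = 10,
  PD = 43, PC = 20, PB = 59, PA2 = 256, PA1 = 221
)

counts_to_groups <- function(counts) rep(names(counts), times = counts)
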