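#' ADL score and band for assessment records
#'
#' The within-category splits of the RUG-III/HC are driven by a summary
#' Activities of Daily Living (ADL) scale: a weighted sum of per-item
#' dependency codes, banded A (lowest dependency) through D (highest) at the
#' configured cut-points. The band is monotone in every item code.
#'
#' @param records A data frame of assessment records (one row per episode)
#'   containing every configured ADL item column.
#' @param config A rule configuration, see [default_rule_config()].
#' @return A tibble with columns `score` (weighted sum) and `band`
#'   (factor with levels A, B, C, D), one row per record.
#' @export
#' @examples
#' config <- default_rule_config()
#' rec <- data.frame(adl_bed_mobility = 1, adl_transfer = 1,
#'                   adl_toilet_use = 1, adl_eating = 1)
#' adl_score(rec, config)
adl_score <- function(records, config) {
  scale <- config$adl_scale
  miss <- setdiff(scale$items, names(records))
  if (length(miss) > 0) {
    stop_classification("missing ADL item column(s): %s",
                        paste(miss, collapse = ", "))
  }
  codes <- as.matrix(records[, scale$items, drop = FALSE])
  if (anyNA(codes)) {
    bad <- scale$items[colSums(is.na(codes)) > 0]
    stop_classification("NA ADL code(s) in item(s): %s",
                        paste(bad, collapse = ", "))
  }
  rng <- scale$code_range
  if (any(codes < rng[1] | codes > rng[2])) {
    bad <- scale$items[colSums(codes < rng[1] | codes > rng[2]) > 0]
    stop_classification("ADL code outside [%d, %d] in item(s): %s",
                        rng[1], rng[2], paste(bad, collapse = ", "))
  }
  score <- drop(codes %*% scale$weights[scale$items])
  band <- cut(score,
              breaks = c(-Inf, scale$band_cuts, Inf),
              labels = c("A", "B", "C", "D"),
              right = TRUE)
  tibble::tibble(score = score, band = band)
}

#' IADL difficulty band
#'
#' Instrumental Activities of Daily Living (IADL) items distinguish the
#' lowest splits of most categories (the x-A1 groups have no IADL
#' difficulty, x-A2 some). The band is `"none"` iff every configured IADL
#' item codes strictly below the difficulty cut-point.
#'
#' @inheritParams adl_score
#' @return Character vector, `"none"` or `"some"`, one per record.
#' @export
iadl_band <- function(records, config) {
  scale <- config$iadl_scale
  miss <- setdiff(scale$items, names(records))
  if (length(miss) > 0) {
    stop_classification("missing IADL item column(s): %s",
                        paste(miss, collapse = ", "))
  }
  codes <- as.matrix(records[, scale$items, drop = FALSE])
  if (anyNA(codes)) {
    bad <- scale$items[colSums(is.na(codes)) > 0]
    stop_classification("NA IADL code(s) in item(s): %s",
                        paste(bad, collapse = ", "))
  }
  rng <- scale$code_range
  if (any(codes < rng[1] | codes > rng[2])) {
    stop_classification("IADL code outside [%d, %d]", rng[1], rng[2])
  }
  ifelse(rowSums(codes >= scale$difficulty_cut) > 0, "some", "none")
}

# Which records satisfy one category trigger (vectorized over rows).
trigger_satisfied <- function(records, trigger) {
  n <- nrow(records)
  switch(trigger$type,
    always = rep(TRUE, n),
    therapy = {
      if (is.null(records$therapy_minutes_7day)) {
        stop_classification("missing column therapy_minutes_7day")
      }
      !is.na(records$therapy_minutes_7day) &
        records$therapy_minutes_7day >= trigger$min_minutes_7day
    },
    cognition = {
      if (is.null(records$cognitive_performance)) {
        stop_classification("missing column cognitive_performance")
      }
      !is.na(records$cognitive_performance) &
        records$cognitive_performance >= trigger$min_score
    },
    clinical_any = rowSums(flag_matrix(records, trigger$flags, "clin_")) > 0,
    behaviour_any = rowSums(flag_matrix(records, trigger$flags, "beh_")) > 0,
    stop_config("unknown trigger type '%s'", trigger$type)
  )
}

# Indicator matrix for a flag list; flags live in 0/1 columns named
# <prefix><flag>. A configured flag without a column is a data defect.
flag_matrix <- function(records, flags, prefix) {
  cols <- paste0(prefix, flags)
  miss <- setdiff(cols, names(records))
  if (length(miss) > 0) {
    stop_classification("missing flag column(s): %s",
                        paste(miss, collapse = ", "))
  }
  m <- as.matrix(records[, cols, drop = FALSE])
  m[is.na(m)] <- 0
  m
}

#' Classify care episodes into RUG-III/HC groups
#'
#' The hierarchical classification algorithm: category triggers are
#' evaluated in hierarchy order (Rehabilitation first, Reduced physical
#' functions the always-true terminal default) and the first satisfied
#' trigger fixes the category; the category's split map then fixes the
#' group from the ADL band, the IADL band and, for Extensive services, the
#' count of distinct extensive services. Every valid record receives
#' exactly one of the 23 groups.
#'
#' `classify_episode()` classifies a single record and returns its group as
#' a one-row tibble; `classify_cohort()` is the vectorized form.
#'
#' @param records A data frame of assessment records; must contain the
#'   configured ADL/IADL item columns, `therapy_minutes_7day`,
#'   `cognitive_performance`, and the configured `clin_*`/`beh_*` flag
#'   columns. An `episode_id` column, when present, is carried through.
#' @param config A rule configuration, see [default_rule_config()].
#' @return A tibble with one row per record: `episode_id` (if supplied),
#'   `group`, `category`, `adl_band`, `iadl_band`.
#' @export
#' @examples
#' config <- default_rule_config()
#' cohort <- generate_cohort(cohort_config(n_episodes = 5, seed = 1))
#' classify_cohort(cohort$assessments, config)
classify_cohort <- function(records, config) {
  validate_rule_config(config)
  if (nrow(records) == 0) {
    return(tibble::tibble(episode_id = character(0), group = character(0),
                          category = character(0), adl_band = character(0),
                          iadl_band = character(0)))
  }
  cats <- rug_categories()$category
  category <- rep(NA_character_, nrow(records))
  for (cat in cats) {  # rank order: first hit wins
    hit <- is.na(category) & trigger_satisfied(records, config$category_triggers[[cat]])
    category[hit] <- cat
  }
  adl <- adl_score(records, config)
  iadl <- iadl_band(records, config)

  ext_flags <- config$category_triggers$ExtensiveServices$flags
  n_services <- rowSums(flag_matrix(records, ext_flags, "clin_"))

  group <- rep(NA_character_, nrow(records))
  for (cat in unique(category)) {
    idx <- which(category == cat)
    rules <- config$split_map[[cat]]
    for (i in idx) {
      group[i] <- resolve_split(rules, as.character(adl$band[i]), iadl[i],
                                n_services[i])
    }
  }
  if (anyNA(group)) {
    stop_config("split_map failed to resolve %d record(s): config defect",
                sum(is.na(group)))
  }
  out <- tibble::tibble(group = group, category = category,
                        adl_band = as.character(adl$band), iadl_band = iadl)
  if (!is.null(records$episode_id)) {
    out <- tibble::add_column(out, episode_id = records$episode_id,
                              .before = 1)
  }
  out
}

#' @rdname classify_cohort
#' @param record A single-row data frame.
#' @export
classify_episode <- function(record, config) {
  if (nrow(record) != 1) {
    stop_data("classify_episode expects exactly one record; got %d",
              nrow(record))
  }
  classify_cohort(record, config)
}

#' Distribution of episodes across RUG-III/HC groups
#'
#' Tabulates classified episodes by group and category, with percentages to
#' one decimal place, category subtotal rows aggregating their groups, and
#' a grand-total row. All 23 groups appear even when empty.
#'
#' @param groups Character vector of group codes (one per episode), e.g.
#'   the `group` column of [classify_cohort()] output.
#' @return A tibble with columns `label` (group code, category name, or
#'   `"Total"`), `level` (`"group"`, `"category"`, `"total"`), `category`,
#'   `count` and `percent` (of the grand total, rounded to 1 d.p.).
#' @export
#' @examples
#' distribution_table(c("CA2", "CA2", "PA1"))
distribution_table <- function(groups) {
  grp <- rug_groups()
  unknown <- setdiff(unique(groups), grp$code)
  if (length(unknown) > 0) {
    stop_data("unknown group code(s): %s", paste(unknown, collapse = ", "))
  }
  total <- length(groups)
  counts <- table(factor(groups, levels = grp$code))
  pct <- function(k) if (total == 0) 0 else round(100 * k / total, 1)

  group_rows <- tibble::tibble(
    label = grp$code, level = "group", category = grp$category,
    count = as.integer(counts[grp$code]),
    percent = pct(as.integer(counts[grp$code]))
  )
  cat_rows <- dplyr::summarise(
    dplyr::group_by(group_rows, category),
    count = sum(count), .groups = "drop"
  )
  cat_rows <- tibble::tibble(
    label = cat_rows$category, level = "category", category = cat_rows$category,
    count = cat_rows$count, percent = pct(cat_rows$count)
  )
  # interleave: category header then its groups, hierarchy order
  out <- dplyr::bind_rows(lapply(rug_categories()$category, function(cat) {
    dplyr::bind_rows(cat_rows[cat_rows$category == cat, ],
                     group_rows[group_rows$category == cat, ])
  }))
  dplyr::bind_rows(out, tibble::tibble(
    label = "Total", level = "total", category = NA_character_,
    count = total, percent = if (total == 0) 0 else 100.0
  ))
}
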