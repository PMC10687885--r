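#' Standardized cost weights from hourly billing rates
#'
#' Hourly rates by discipline are standardized by the personal support
#' worker (PSW) rate, the reference discipline, yielding dimensionless cost
#' weights with `weight["PSW"] == 1` exactly. Unpaid caregiving is valued
#' by replacement cost at the PSW rate, i.e. a weight of 1.00 per unpaid
#' hour, so downstream "cost" is expressed in PSW-hour equivalents and is
#' invariant to rescaling all rates by a common factor.
#'
#' @param rates Named numeric vector of hourly rates (currency/hour), one
#'   per discipline; must include `PSW` and be strictly positive.
#' @param unpaid_weight Weight per hour of unpaid care; default 1.0.
#' @return A list of class `cost_weight_table` with elements `hourly_rate`,
#'   `weight` and `unpaid_weight`.
#' @export
#' @examples
#' standardize_weights(c(PSW = 25, RN = 50, RPN = 35))$weight
standardize_weights <- function(rates, unpaid_weight = 1.0) {
  if (is.null(names(rates)) || any(names(rates) == "")) {
    stop_config("rates must be a named vector of disciplines")
  }
  if (!"PSW" %in% names(rates)) {
    stop_config("rates must include the PSW reference discipline")
  }
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    stop_config("all hourly rates must be positive and finite")
  }
  if (unpaid_weight <= 0) stop_config("unpaid_weight must be positive")
  structure(list(hourly_rate = rates,
                 weight = rates / rates[["PSW"]],
                 unpaid_weight = unpaid_weight),
            class = "cost_weight_table")
}

#' Default cost-weight table
#'
#' Representative Ontario home care hourly billing rates (fair market
#' value of labour, including indirect employment costs), standardized by
#' the PSW rate. The absolute currency values never reach downstream
#' computations — only the ratios do.
#'
#' @return A `cost_weight_table`.
#' @export
default_cost_weights <- function() {
  standardize_weights(c(RPN = 55, RN = 75, OT = 110, PT = 110, SLP = 115,
                        SW = 95, RD = 100, PTA = 60, PSW = 35))
}

#' Paid care time and cost for one episode
#'
#' Aggregates an episode's billing records: paid hours are the plain sum;
#' paid cost multiplies each discipline's hours by its standardized cost
#' weight before summing, giving PSW-hour equivalents.
#'
#' @param billing Data frame of billing records for one episode, columns
#'   `discipline` and `hours`.
#' @param weights A [standardize_weights()] table covering every
#'   discipline that appears.
#' @return Named numeric vector `c(paid_hours, paid_cost)`.
#' @export
#' @examples
#' w <- standardize_weights(c(PSW = 25, RN = 50))
#' paid_measures(data.frame(discipline = c("PSW", "RN"), hours = c(3, 4)), w)
paid_measures <- function(billing, weights) {
  if (nrow(billing) == 0) return(c(paid_hours = 0, paid_cost = 0))
  unknown <- setdiff(unique(billing$discipline), names(weights$weight))
  if (length(unknown) > 0) {
    stop_data("billing contains discipline(s) without a cost weight: %s",
              paste(unknown, collapse = ", "))
  }
  if (any(is.na(billing$hours)) || any(billing$hours < 0)) {
    stop_data("billing hours must be non-negative")
  }
  c(paid_hours = sum(billing$hours),
    paid_cost = sum(billing$hours * weights$weight[billing$discipline]))
}

#' Estimate total unpaid caregiving hours over an episode
#'
#' Clients self-report unpaid care received in the preceding 3 days at
#' admission and (when available) at discharge. The episode total is the
#' mean of the two 3-day reports converted to a daily rate (divided by 3)
#' and multiplied by the episode length; with no discharge report the
#' admission report alone is used.
#'
#' @param adm_3day Admission 3-day unpaid hours (>= 0). Vectorized.
#' @param dis_3day Discharge 3-day unpaid hours, or `NA` when absent.
#' @param episode_days Episode length in days (>= 1).
#' @return Estimated unpaid hours over the episode.
#' @export
#' @examples
#' estimate_unpaid_hours(6, 12, 100)   # ((6 + 12) / 2) / 3 * 100 = 300
#' estimate_unpaid_hours(9, NA, 30)    # 9 / 3 * 30 = 90
estimate_unpaid_hours <- function(adm_3day, dis_3day, episode_days) {
  if (any(is.na(adm_3day)) || any(adm_3day < 0) ||
      any(dis_3day < 0, na.rm = TRUE)) {
    stop_data("unpaid 3-day reports must be non-negative (admission required)")
  }
  if (any(is.na(episode_days)) || any(episode_days < 1)) {
    stop_data("episode_days must be >= 1")
  }
  mean_3day <- ifelse(is.na(dis_3day), adm_3day, (adm_3day + dis_3day) / 2)
  mean_3day / 3 * episode_days
}

#' Per-episode utilization measures
#'
#' Assembles the four resource-utilization measures for every episode with
#' at least one billing record: paid hours, paid cost (PSW-hour
#' equivalents), and combined paid + unpaid time and cost, with unpaid
#' hours estimated by [estimate_unpaid_hours()] and valued at
#' `weights$unpaid_weight`. Episodes without billing records are excluded
#' (they remain classifiable; the exclusion count is recorded in the
#' `n_missing_billing` attribute).
#'
#' @param assessments Assessment table (needs `episode_id`,
#'   `episode_start`, `episode_end`, `unpaid_hours_3day_admission`,
#'   `unpaid_hours_3day_discharge`).
#' @param billing Billing table (`episode_id`, `discipline`, `hours`).
#' @param weights A [standardize_weights()] table.
#' @return Tibble with columns `episode_id`, `episode_days`, `paid_hours`,
#'   `paid_cost`, `unpaid_hours`, `total_hours`, `total_cost`.
#' @export
episode_measures <- function(assessments, billing,
                             weights = default_cost_weights()) {
  if (nrow(assessments) == 0) {
    return(structure(tibble::tibble(
      episode_id = character(0), episode_days = integer(0),
      paid_hours = numeric(0), paid_cost = numeric(0),
      unpaid_hours = numeric(0), total_hours = numeric(0),
      total_cost = numeric(0)), n_missing_billing = 0L))
  }
  unknown <- setdiff(unique(billing$discipline), names(weights$weight))
  if (length(unknown) > 0) {
    stop_data("billing contains discipline(s) without a cost weight: %s",
              paste(unknown, collapse = ", "))
  }
  paid <- dplyr::summarise(
    dplyr::group_by(billing, .data$episode_id),
    paid_hours = sum(.data$hours),
    paid_cost = sum(.data$hours * weights$weight[.data$discipline]),
    .groups = "drop")

  days <- as.integer(assessments$episode_end - assessments$episode_start)
  if (any(days < 0)) stop_data("episode_end precedes episode_start")
  measures <- tibble::tibble(
    episode_id = assessments$episode_id,
    episode_days = pmax(days, 1L),
    unpaid_hours = estimate_unpaid_hours(
      assessments$unpaid_hours_3day_admission,
      assessments$unpaid_hours_3day_discharge,
      pmax(days, 1L))
  )
  measures <- dplyr::inner_join(measures, paid, by = "episode_id")
  measures$total_hours <- measures$paid_hours + measures$unpaid_hours
  measures$total_cost <- measures$paid_cost +
    weights$unpaid_weight * measures$unpaid_hours
  out <- measures[, c("episode_id", "episode_days", "paid_hours",
                      "paid_cost", "unpaid_hours", "total_hours",
                      "total_cost")]
  attr(out, "n_missing_billing") <- nrow(assessments) - nrow(out)
  out
}

#' Trim episode-length outliers: the operational sample
#'
#' Removes episodes whose length falls strictly below the `low_pct`
#' quantile or strictly above the `1 - high_pct` quantile of episode
#' length, producing the "operational" sample that reflects the intended
#' duration of a transitional care program (defaults: lowest 1% and
#' highest 5% removed).
#'
#' @param episodes Data frame with an `episode_days` column.
#' @param low_pct,high_pct Trim fractions in \[0, 1\) with
#'   `low_pct + high_pct < 1`.
#' @param type Quantile convention passed to [stats::quantile()]; default
#'   7, inclusive linear interpolation.
#' @return The retained subset, same columns, with attribute `n_trimmed`.
#' @export
#' @examples
#' df <- data.frame(episode_days = 1:100)
#' nrow(trim_operational(df))  # 94: length 1 and lengths 96-100 removed
trim_operational <- function(episodes, low_pct = 0.01, high_pct = 0.05,
                             type = 7) {
  if (is.na(low_pct) || is.na(high_pct) || low_pct < 0 || high_pct < 0 ||
      low_pct + high_pct >= 1) {
    stop_config("trim fractions must be non-negative with low_pct + high_pct < 1")
  }
  if (is.null(episodes$episode_days)) {
    stop_data("episodes must carry an episode_days column")
  }
  if (nrow(episodes) == 0 || (low_pct == 0 && high_pct == 0)) {
    attr(episodes, "n_trimmed") <- 0L
    return(episodes)
  }
  x <- episodes$episode_days
  lo <- stats::quantile(x, low_pct, type = type, names = FALSE)
  hi <- stats::quantile(x, 1 - high_pct, type = type, names = FALSE)
  keep <- x >= lo & x <= hi
  out <- episodes[keep, , drop = FALSE]
  attr(out, "n_trimmed") <- sum(!keep)
  out
}
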