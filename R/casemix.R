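#' Coefficient of variation
#'
#' Within-group homogeneity measure: standard deviation divided by the
#' mean. The sample SD (n - 1 denominator) is used by default; a single
#' value has SD 0 by convention, and an all-zero input returns 0.
#'
#' @param values Non-negative numeric vector, length >= 1.
#' @param population Use the population (n denominator) SD instead.
#' @return Dimensionless ratio.
#' @export
#' @examples
#' cv(c(1, 2, 3))  # sample SD 1, mean 2 -> 0.5
cv <- function(values, population = FALSE) {
  if (length(values) == 0 || anyNA(values)) {
    stop_data("cv requires at least one non-missing value")
  }
  if (any(values < 0)) stop_data("cv is defined here for non-negative values")
  m <- mean(values)
  if (m == 0) return(0)  # non-negative values with zero mean are all zero
  s <- if (length(values) == 1) 0 else stats::sd(values)
  if (population) s <- s * sqrt((length(values) - 1) / length(values))
  s / m
}

#' The four utilization measures
#' @return Character vector of measure column names.
#' @export
utilization_measures <- function() {
  c("paid_hours", "paid_cost", "total_hours", "total_cost")
}

#' Case-mix table: group means, SDs, CMIs and CVs
#'
#' For each of the 23 RUG-III/HC groups and each of the four utilization
#' measures (paid time, paid cost, combined paid + unpaid time and cost),
#' computes the group n, mean, SD, case-mix index (CMI — the group mean
#' divided by the overall population mean, a dimensionless relative
#' resource weight) and coefficient of variation. Groups with no episodes
#' are reported as NA; groups with fewer than 10 episodes are flagged
#' unstable. An overall row carries CMI exactly 1 for every measure by
#' construction, and the n-weighted mean of group CMIs is 1.
#'
#' @param measures Tibble from [episode_measures()].
#' @param groups Tibble mapping `episode_id` to `group` (e.g.
#'   [classify_cohort()] output).
#' @param sample_label `"full"` or `"operational"`, recorded on the table.
#' @param population Use the population SD (default: sample SD, n - 1).
#' @return A tibble with one row per group plus an `"Overall"` row:
#'   columns `group`, `category`, `n`, `unstable`, and
#'   `mean_*`, `sd_*`, `cmi_*`, `cv_*` for each measure. The label is in
#'   attribute `sample_label`.
#' @export
case_mix_table <- function(measures, groups, sample_label = "full",
                           population = FALSE) {
  if (nrow(measures) == 0) stop_data("no episodes with utilization measures")
  df <- dplyr::inner_join(measures, groups[, c("episode_id", "group")],
                          by = "episode_id")
  if (nrow(df) < nrow(measures)) {
    stop_data("%d episode(s) with measures lack a group assignment",
              nrow(measures) - nrow(df))
  }
  grp <- rug_groups()
  ms <- utilization_measures()
  sd_fun <- function(x) {
    if (length(x) == 1) return(0)
    s <- stats::sd(x)
    if (population) s * sqrt((length(x) - 1) / length(x)) else s
  }

  overall_mean <- vapply(ms, function(m) mean(df[[m]]), numeric(1))
  rows <- lapply(grp$code, function(g) {
    sub <- df[df$group == g, , drop = FALSE]
    n <- nrow(sub)
    row <- tibble::tibble(group = g,
                          category = grp$category[grp$code == g],
                          n = n, unstable = n > 0 & n < 10)
    for (m in ms) {
      if (n == 0) {
        row[[paste0("mean_", m)]] <- NA_real_
        row[[paste0("sd_", m)]] <- NA_real_
        row[[paste0("cmi_", m)]] <- NA_real_
        row[[paste0("cv_", m)]] <- NA_real_
      } else {
        mu <- mean(sub[[m]])
        row[[paste0("mean_", m)]] <- mu
        row[[paste0("sd_", m)]] <- sd_fun(sub[[m]])
        row[[paste0("cmi_", m)]] <- mu / overall_mean[[m]]
        row[[paste0("cv_", m)]] <- cv(sub[[m]], population = population)
      }
    }
    row
  })
  overall <- tibble::tibble(group = "Overall", category = NA_character_,
                            n = nrow(df), unstable = FALSE)
  for (m in ms) {
    overall[[paste0("mean_", m)]] <- overall_mean[[m]]
    overall[[paste0("sd_", m)]] <- sd_fun(df[[m]])
    overall[[paste0("cmi_", m)]] <- 1
    overall[[paste0("cv_", m)]] <- cv(df[[m]], population = population)
  }
  out <- dplyr::bind_rows(overall, dplyr::bind_rows(rows))
  attr(out, "sample_label") <- sample_label
  out
}

#' Render a case-mix table for display
#'
#' Formats a [case_mix_table()] the way such tables are printed: one row
#' per group, `n`, and `CMI (CV)` pairs rounded to 2 decimals for the four
#' measures, `NA` for empty groups.
#'
#' @param table A [case_mix_table()].
#' @return A tibble of formatted character columns.
#' @export
format_case_mix_table <- function(table) {
  ms <- utilization_measures()
  fmt <- function(cmi, cvv) {
    ifelse(is.na(cmi), "NA", sprintf("%.2f (%.2f)", cmi, cvv))
  }
  out <- tibble::tibble(group = table$group, n = table$n)
  labels <- c(paid_hours = "paid_time", paid_cost = "paid_cost",
              total_hours = "combined_time", total_cost = "combined_cost")
  for (m in ms) {
    out[[paste0(labels[[m]], "_cmi_cv")]] <-
      fmt(table[[paste0("cmi_", m)]], table[[paste0("cv_", m)]])
  }
  out
}
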