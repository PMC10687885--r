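#' Attach group CMIs to episode records as predictors
#'
#' Each episode receives, for each of the four utilization measures, the
#' case-mix index of its RUG-III/HC group — the predictor used when
#' evaluating how much utilization variance the classification explains.
#' Episodes whose group has an undefined (NA) CMI are excluded; the count
#' is recorded in the `n_excluded` attribute.
#'
#' @param measures Tibble from [episode_measures()].
#' @param groups Tibble mapping `episode_id` to `group`.
#' @param table A [case_mix_table()] supplying the CMIs.
#' @return `measures` augmented with `group` and `cmi_<measure>` columns.
#' @export
attach_cmi <- function(measures, groups, table) {
  df <- dplyr::inner_join(measures, groups[, c("episode_id", "group")],
                          by = "episode_id")
  cmi_cols <- paste0("cmi_", utilization_measures())
  lut <- table[table$group != "Overall", c("group", cmi_cols)]
  df <- dplyr::left_join(df, lut, by = "group")
  ok <- stats::complete.cases(df[, cmi_cols])
  out <- df[ok, , drop = FALSE]
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Coefficient of determination of a linear model
#'
#' Ordinary least squares with intercept; categorical predictors are
#' encoded as dummy indicators against a reference level. When the single
#' predictor is the group-mean-derived CMI fitted on the sample that
#' produced it, the R-squared equals the between-group share of the total
#' sum of squares (eta-squared).
#'
#' @param outcome Numeric outcome vector (>= 2 distinct values).
#' @param predictors Data frame (or vector) of predictor columns.
#' @return R-squared in \[0, 1\].
#' @export
#' @examples
#' r_squared(c(1, 2, 3, 4), data.frame(x = c(1, 2, 3, 4)))  # 1
r_squared <- function(outcome, predictors) {
  if (!is.data.frame(predictors)) predictors <- data.frame(x = predictors)
  if (length(outcome) != nrow(predictors)) {
    stop_data("outcome and predictors disagree on length")
  }
  if (length(unique(outcome)) < 2) {
    stop_model("outcome has fewer than 2 distinct values")
  }
  degenerate <- vapply(predictors, function(p) length(unique(p)) < 2,
                       logical(1))
  if (all(degenerate)) {
    stop_model("all predictors are constant (zero-variance design)")
  }
  df <- data.frame(.outcome = outcome, predictors)
  fit <- stats::lm(.outcome ~ ., data = df)
  if (any(is.na(stats::coef(fit)[-1]))) {
    aliased <- names(stats::coef(fit))[-1][is.na(stats::coef(fit)[-1])]
    stop_model("rank-deficient design; aliased term(s): %s",
               paste(aliased, collapse = ", "))
  }
  summary(fit)$r.squared
}

#' Variance in utilization explained by the case-mix system
#'
#' The evaluation grid: for each of the four utilization measures, each
#' sample (full and operational) and each model (the group CMI alone, or
#' the CMI plus a program indicator), fit a linear regression of the
#' episode-level measure on the predictors and report the variance
#' explained (unadjusted R-squared). By default CMIs are recomputed within
#' each sample before fitting (`refit_cmi = TRUE`); the program factor's
#' reference level is the largest program. Adding the program indicator
#' can only increase R-squared (nested models).
#'
#' @param full_measures,operational_measures [episode_measures()] tibbles
#'   for the full and trimmed samples.
#' @param groups Tibble mapping `episode_id` to `group`.
#' @param programs Tibble mapping `episode_id` to `program_id`.
#' @param refit_cmi Recompute CMIs within each sample (default) or reuse
#'   the full-sample CMIs for both.
#' @return Tibble with columns `measure`, `model`
#'   (`cmi_only` / `cmi_plus_program`), `sample` (`full` /
#'   `operational`), `r_squared` and `n_used` — 16 rows.
#' @export
evaluation_table <- function(full_measures, operational_measures, groups,
                             programs, refit_cmi = TRUE) {
  if (nrow(full_measures) == 0 || nrow(operational_measures) == 0) {
    stop_data("both samples must be non-empty")
  }
  full_table <- case_mix_table(full_measures, groups, "full")
  samples <- list(
    full = list(measures = full_measures, table = full_table),
    operational = list(
      measures = operational_measures,
      table = if (refit_cmi) {
        case_mix_table(operational_measures, groups, "operational")
      } else {
        full_table
      })
  )
  rows <- list()
  for (sample_label in names(samples)) {
    s <- samples[[sample_label]]
    aug <- attach_cmi(s$measures, groups, s$table)
    aug <- dplyr::inner_join(aug, programs[, c("episode_id", "program_id")],
                             by = "episode_id")
    prog_levels <- names(sort(table(aug$program_id), decreasing = TRUE))
    aug$program <- droplevels(factor(aug$program_id, levels = prog_levels))
    for (m in utilization_measures()) {
      cmi_col <- paste0("cmi_", m)
      r2_cmi <- r_squared(aug[[m]], data.frame(cmi = aug[[cmi_col]]))
      preds <- data.frame(cmi = aug[[cmi_col]], program = aug$program)
      r2_both <- if (nlevels(droplevels(aug$program)) > 1) {
        r_squared(aug[[m]], preds)
      } else {
        r2_cmi  # a single program adds nothing to the design
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        measure = m,
        model = c("cmi_only", "cmi_plus_program"),
        sample = sample_label,
        r_squared = c(r2_cmi, r2_both),
        n_used = nrow(aug))
    }
  }
  dplyr::bind_rows(rows)
}
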