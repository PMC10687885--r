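#' Write and read cohort tables as CSV
#'
#' The interchange format is plain CSV (comma-separated, UTF-8, mandatory
#' header row, ISO-8601 dates). `write_cohort()` emits
#' `assessments.csv` and `billing.csv` into a directory; `read_cohort()`
#' reads and validates them back. Unknown columns are kept with a warning;
#' rows that fail validation (negative hours, unknown discipline, end
#' before start) are dropped and reported together in the
#' `row_failures` attribute.
#'
#' @param cohort List with `assessments` and `billing` tables.
#' @param dir Output directory (created if needed).
#' @param assessments_path,billing_path CSV file paths.
#' @return `write_cohort()` returns the two paths invisibly;
#'   `read_cohort()` returns a list with `assessments` and `billing`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ap <- file.path(dir, "assessments.csv")
  bp <- file.path(dir, "billing.csv")
  utils::write.csv(cohort$assessments, ap, row.names = FALSE, na = "")
  utils::write.csv(cohort$billing, bp, row.names = FALSE, na = "")
  invisible(c(assessments = ap, billing = bp))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(assessments_path, billing_path) {
  for (p in c(assessments_path, billing_path)) {
    if (!file.exists(p)) stop_parse("input file not found: %s", p)
  }
  assessments <- tibble::as_tibble(
    utils::read.csv(assessments_path, stringsAsFactors = FALSE))
  billing <- tibble::as_tibble(
    utils::read.csv(billing_path, stringsAsFactors = FALSE))

  mandatory_a <- c("episode_id", "episode_start", "episode_end",
                   "unpaid_hours_3day_admission")
  miss <- setdiff(mandatory_a, names(assessments))
  if (length(miss) > 0) {
    stop_parse("assessments missing mandatory column(s): %s",
               paste(miss, collapse = ", "))
  }
  mandatory_b <- c("episode_id", "discipline", "hours")
  miss <- setdiff(mandatory_b, names(billing))
  if (length(miss) > 0) {
    stop_parse("billing missing mandatory column(s): %s",
               paste(miss, collapse = ", "))
  }
  assessments$episode_start <- as.Date(assessments$episode_start)
  assessments$episode_end <- as.Date(assessments$episode_end)
  if (!"unpaid_hours_3day_discharge" %in% names(assessments)) {
    assessments$unpaid_hours_3day_discharge <- NA_real_
  }

  failures <- character(0)
  bad_a <- which(is.na(assessments$episode_start) |
                 is.na(assessments$episode_end) |
                 assessments$episode_end < assessments$episode_start |
                 is.na(assessments$unpaid_hours_3day_admission) |
                 assessments$unpaid_hours_3day_admission < 0)
  if (length(bad_a) > 0) {
    failures <- c(failures,
                  sprintf("assessments row %d: invalid dates or unpaid report",
                          bad_a))
    assessments <- assessments[-bad_a, , drop = FALSE]
  }
  bad_b <- which(is.na(billing$hours) | billing$hours < 0 |
                 !(billing$discipline %in% rug_disciplines()))
  if (length(bad_b) > 0) {
    failures <- c(failures,
                  sprintf("billing row %d: invalid hours or discipline",
                          bad_b))
    billing <- billing[-bad_b, , drop = FALSE]
  }
  out <- list(assessments = assessments, billing = billing)
  attr(out, "row_failures") <- failures
  if (length(failures) > 0) {
    warning(sprintf("%d row(s) failed validation and were dropped",
                    length(failures)), call. = FALSE)
  }
  out
}

#' Cohort summary table
#'
#' Per-sample descriptive statistics in the shape of a population
#' characteristics table: episode count, episode length, paid hours per
#' episode overall and by discipline, and unpaid hours per episode.
#'
#' @param assessments,billing Cohort tables.
#' @param measures An [episode_measures()] tibble for the same episodes.
#' @return Tibble with `characteristic`, `mean`, `sd`.
#' @export
cohort_summary <- function(assessments, billing, measures) {
  by_disc <- dplyr::summarise(
    dplyr::group_by(billing, .data$discipline),
    total = sum(.data$hours), .groups = "drop")
  n_billed <- length(unique(billing$episode_id))
  rows <- list(
    tibble::tibble(characteristic = "care_episodes",
                   mean = nrow(assessments), sd = NA_real_),
    tibble::tibble(characteristic = "episode_days",
                   mean = mean(measures$episode_days),
                   sd = stats::sd(measures$episode_days)),
    tibble::tibble(characteristic = "paid_hours",
                   mean = mean(measures$paid_hours),
                   sd = stats::sd(measures$paid_hours)),
    tibble::tibble(characteristic = "unpaid_hours",
                   mean = mean(measures$unpaid_hours),
                   sd = stats::sd(measures$unpaid_hours))
  )
  disc_rows <- lapply(rug_disciplines(), function(d) {
    hrs <- billing$hours[billing$discipline == d]
    per_episode <- sum(hrs) / max(n_billed, 1)
    tibble::tibble(characteristic = paste0("paid_hours_", d),
                   mean = per_episode, sd = NA_real_)
  })
  dplyr::bind_rows(c(rows, disc_rows))
}

#' Run the full case-mix analysis pipeline
#'
#' Orchestrates every stage: obtain a cohort (synthetic via
#' [generate_cohort()] or from CSV files), classify episodes into
#' RUG-III/HC groups, compute utilization measures, derive the full and
#' operational (length-trimmed) samples, build distribution, case-mix and
#' variance-evaluation tables for both samples, and write all artifacts
#' plus a run manifest into the output directory.
#'
#' @param out_dir Output directory.
#' @param cohort_cfg A [cohort_config()] for synthetic mode, or `NULL`.
#' @param assessments_path,billing_path CSV inputs for file mode (exactly
#'   one of file mode / synthetic mode must be used).
#' @param rules Rule configuration (default [default_rule_config()]).
#' @param weights Cost-weight table (default [default_cost_weights()]).
#' @param low_trim,high_trim Trim fractions for the operational sample.
#' @param seed Seed for synthetic mode (overrides the config's seed when
#'   given).
#' @return Invisibly, a list with every computed table and the manifest.
#' @export
run_pipeline <- function(out_dir,
                         cohort_cfg = NULL,
                         assessments_path = NULL, billing_path = NULL,
                         rules = default_rule_config(),
                         weights = default_cost_weights(),
                         low_trim = 0.01, high_trim = 0.05,
                         seed = NULL) {
  synthetic <- !is.null(cohort_cfg)
  file_mode <- !is.null(assessments_path) || !is.null(billing_path)
  if (synthetic == file_mode) {
    stop_config("supply exactly one of cohort_cfg or assessment/billing paths")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (synthetic) {
    if (!is.null(seed)) cohort_cfg$seed <- as.integer(seed)
    cohort <- generate_cohort(cohort_cfg, rules)
    write_cohort(cohort, out_dir)
  } else {
    cohort <- read_cohort(assessments_path, billing_path)
  }
  assessments <- cohort$assessments
  billing <- cohort$billing

  groups <- classify_cohort(assessments, rules)
  utils::write.csv(groups, file.path(out_dir, "classification.csv"),
                   row.names = FALSE)

  measures_full <- episode_measures(assessments, billing, weights)
  measures_oper <- trim_operational(measures_full, low_trim, high_trim)

  # distribution over ALL classified episodes (classification does not need
  # billing); the operational distribution trims on episode length of the
  # full assessment set
  days_all <- pmax(as.integer(assessments$episode_end - assessments$episode_start), 1L)
  trim_all <- trim_operational(
    tibble::tibble(episode_id = assessments$episode_id,
                   episode_days = days_all),
    low_trim, high_trim)
  dist_full <- distribution_table(groups$group)
  dist_oper <- distribution_table(
    groups$group[groups$episode_id %in% trim_all$episode_id])
  utils::write.csv(dist_full, file.path(out_dir, "distribution_full.csv"),
                   row.names = FALSE)
  utils::write.csv(dist_oper,
                   file.path(out_dir, "distribution_operational.csv"),
                   row.names = FALSE)

  empty_casemix <- nrow(measures_full) == 0
  if (empty_casemix) {
    warning("no episodes with billing records; case-mix and evaluation stages skipped",
            call. = FALSE)
    cm_full <- cm_oper <- eval_table <- NULL
    for (f in c("casemix_full.csv", "casemix_operational.csv",
                "evaluation.csv")) {
      utils::write.csv(data.frame(), file.path(out_dir, f),
                       row.names = FALSE)
    }
  } else {
    cm_full <- case_mix_table(measures_full, groups, "full")
    cm_oper <- case_mix_table(measures_oper, groups, "operational")
    utils::write.csv(cm_full, file.path(out_dir, "casemix_full.csv"),
                     row.names = FALSE, na = "NA")
    utils::write.csv(cm_oper, file.path(out_dir, "casemix_operational.csv"),
                     row.names = FALSE, na = "NA")
    programs <- assessments[, c("episode_id", "program_id")]
    eval_table <- evaluation_table(measures_full, measures_oper, groups,
                                   programs)
    eval_out <- eval_table
    eval_out$r_squared_pct <- sprintf("%.2f", 100 * eval_out$r_squared)
    utils::write.csv(eval_out, file.path(out_dir, "evaluation.csv"),
                     row.names = FALSE)
  }

  summary_tbl <- cohort_summary(assessments, billing, measures_full)
  utils::write.csv(summary_tbl, file.path(out_dir, "cohort_summary.csv"),
                   row.names = FALSE)

  manifest <- list(
    mode = if (synthetic) "synthetic" else "files",
    seed = if (synthetic) cohort_cfg$seed else NA,
    n_episodes = nrow(assessments),
    n_classified = nrow(groups),
    n_with_billing = nrow(measures_full),
    n_missing_billing = attr(measures_full, "n_missing_billing"),
    n_operational = nrow(measures_oper),
    n_trimmed = attr(measures_oper, "n_trimmed"),
    low_trim = low_trim, high_trim = high_trim,
    config_hash = if (synthetic) {
      config_hash(cohort_cfg)
    } else {
      config_hash(list(assessments_path, billing_path))
    }
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")

  invisible(list(assessments = assessments, billing = billing,
                 groups = groups,
                 measures_full = measures_full,
                 measures_operational = measures_oper,
                 distribution_full = dist_full,
                 distribution_operational = dist_oper,
                 casemix_full = cm_full, casemix_operational = cm_oper,
                 evaluation = eval_table, summary = summary_tbl,
                 manifest = manifest))
}

# order-stable fingerprint of a configuration, for the run manifest
config_hash <- function(x) {
  serialized <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                 force = TRUE)
  # small polynomial rolling hash over the serialized text (kept in double
  # precision, exact below 2^53): no extra dependency needed
  bytes <- utf8ToInt(as.character(serialized))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}
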