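#' RUG-III/HC category and group vocabularies
#'
#' The RUG-III/HC system arranges home care clients into 7 clinical
#' categories, evaluated in a fixed hierarchy (rank 1 is considered first),
#' and subdivides each category into groups by functional dependency, for
#' 23 groups in all. `rug_categories()` returns the categories in hierarchy
#' order; `rug_groups()` returns the full group table with each group's
#' category and its within-category rank (1 = highest expected resource
#' use).
#'
#' @return A tibble. For `rug_categories()`: columns `category` and `rank`.
#'   For `rug_groups()`: columns `code`, `category` and
#'   `within_category_rank`.
#' @export
#' @examples
#' rug_categories()
#' rug_groups()
rug_categories <- function() {
  tibble::tibble(
    category = c("Rehabilitation", "ExtensiveServices", "SpecialCare",
                 "ClinicallyComplex", "ImpairedCognition",
                 "BehaviourProblems", "ReducedPhysicalFunctions"),
    rank = 1:7
  )
}

#' @rdname rug_categories
#' @export
rug_groups <- function() {
  tibble::tibble(
    code = c("RB", "RA2", "RA1",
             "SE3", "SE2", "SE1",
             "SSB", "SSA",
             "CC", "CB", "CA2", "CA1",
             "IB", "IA2", "IA1",
             "BB", "BA2", "BA1",
             "PD", "PC", "PB", "PA2", "PA1"),
    category = rep(rug_categories()$category, times = c(3, 3, 2, 4, 3, 3, 5)),
    within_category_rank = c(1:3, 1:3, 1:2, 1:4, 1:3, 1:3, 1:5)
  )
}

#' The nine provider disciplines of the billing vocabulary
#'
#' Registered practical nurse (RPN), registered nurse (RN), occupational
#' therapist (OT), physical therapist (PT), speech-language pathologist
#' (SLP), social worker (SW), registered dietitian (RD), physical therapy
#' assistant (PTA), and personal support worker (PSW). PSW is the reference
#' discipline for cost standardization.
#'
#' @return Character vector of discipline codes.
#' @export
rug_disciplines <- function() {
  c("RPN", "RN", "OT", "PT", "SLP", "SW", "RD", "PTA", "PSW")
}

#' Default classification rule configuration
#'
#' The hierarchical skeleton of the RUG-III/HC grouper (category order and
#' ADL/IADL splits) is fixed by the system; the clinical triggers that admit
#' a client to each category are item-level definitions that vary with the
#' assessment instrument, so they are data rather than code: this function
#' returns the package default, and [read_rule_config()] /
#' [write_rule_config()] round-trip an editable YAML form.
#'
#' The default rules:
#' \describe{
#'   \item{Rehabilitation}{therapy minutes in the last 7 days >= 120.}
#'   \item{ExtensiveServices}{any of IV medication, tracheostomy care,
#'     ventilator; the SE3/SE2/SE1 split counts distinct extensive
#'     services (3+/2/1).}
#'   \item{SpecialCare}{any of a named flag list (stage 3+ pressure ulcer,
#'     tube feeding, radiation therapy, multiple sclerosis, quadriplegia).}
#'   \item{ClinicallyComplex}{any of pneumonia, dehydration, wound care,
#'     oxygen therapy, chemotherapy, dialysis, end-stage disease.}
#'   \item{ImpairedCognition}{cognitive performance score >= 3.}
#'   \item{BehaviourProblems}{any behaviour flag.}
#'   \item{ReducedPhysicalFunctions}{always true (terminal default).}
#' }
#'
#' The ADL scale is a 4-item sum (bed mobility, transfer, toilet use,
#' eating), each item coded 1-5, banded A (4-7), B (8-11), C (12-15),
#' D (16-20); band A is "low ADL limitations". The IADL scale flags "some
#' difficulty" when any of 5 items (meal preparation, housework, phone use,
#' managing medications, managing finances; codes 0-3) is at or above the
#' difficulty cut-point of 1. Within every category except Extensive
#' services, the split assigns the x-A1 group to band A with no IADL
#' difficulty, x-A2 to band A with some IADL difficulty, and the higher
#' groups to bands B/C/D.
#'
#' @return A list of class `rug_rule_config` with elements `adl_scale`,
#'   `iadl_scale`, `category_triggers` and `split_map`.
#' @seealso [classify_episode()], [validate_rule_config()]
#' @export
default_rule_config <- function() {
  config <- list(
    adl_scale = list(
      items = c("adl_bed_mobility", "adl_transfer", "adl_toilet_use",
                "adl_eating"),
      weights = c(adl_bed_mobility = 1, adl_transfer = 1,
                  adl_toilet_use = 1, adl_eating = 1),
      code_range = c(1L, 5L),
      # upper score bound of bands A, B, C; anything above is D
      band_cuts = c(A = 7, B = 11, C = 15)
    ),
    iadl_scale = list(
      items = c("iadl_meal_preparation", "iadl_housework", "iadl_phone_use",
                "iadl_managing_medications", "iadl_managing_finances"),
      code_range = c(0L, 3L),
      difficulty_cut = 1L
    ),
    category_triggers = list(
      Rehabilitation = list(type = "therapy", min_minutes_7day = 120),
      ExtensiveServices = list(
        type = "clinical_any",
        flags = c("iv_medication", "tracheostomy_care", "ventilator")
      ),
      SpecialCare = list(
        type = "clinical_any",
        flags = c("pressure_ulcer_stage3plus", "tube_feeding",
                  "radiation_therapy", "multiple_sclerosis", "quadriplegia")
      ),
      ClinicallyComplex = list(
        type = "clinical_any",
        flags = c("pneumonia", "dehydration", "wound_care", "oxygen_therapy",
                  "chemotherapy", "dialysis", "end_stage_disease")
      ),
      ImpairedCognition = list(type = "cognition", min_score = 3),
      BehaviourProblems = list(
        type = "behaviour_any",
        flags = c("wandering", "verbally_abusive", "physically_abusive",
                  "socially_inappropriate", "resists_care")
      ),
      ReducedPhysicalFunctions = list(type = "always")
    ),
    split_map = list(
      Rehabilitation = list(
        list(adl_bands = c("B", "C", "D"), group = "RB"),
        list(adl_bands = "A", iadl = "some", group = "RA2"),
        list(adl_bands = "A", iadl = "none", group = "RA1")
      ),
      ExtensiveServices = list(
        list(min_services = 3, group = "SE3"),
        list(min_services = 2, group = "SE2"),
        list(min_services = 1, group = "SE1")
      ),
      SpecialCare = list(
        list(adl_bands = c("B", "C", "D"), group = "SSB"),
        list(adl_bands = "A", group = "SSA")
      ),
      ClinicallyComplex = list(
        list(adl_bands = c("C", "D"), group = "CC"),
        list(adl_bands = "B", group = "CB"),
        list(adl_bands = "A", iadl = "some", group = "CA2"),
        list(adl_bands = "A", iadl = "none", group = "CA1")
      ),
      ImpairedCognition = list(
        list(adl_bands = c("B", "C", "D"), group = "IB"),
        list(adl_bands = "A", iadl = "some", group = "IA2"),
        list(adl_bands = "A", iadl = "none", group = "IA1")
      ),
      BehaviourProblems = list(
        list(adl_bands = c("B", "C", "D"), group = "BB"),
        list(adl_bands = "A", iadl = "some", group = "BA2"),
        list(adl_bands = "A", iadl = "none", group = "BA1")
      ),
      ReducedPhysicalFunctions = list(
        list(adl_bands = "D", group = "PD"),
        list(adl_bands = "C", group = "PC"),
        list(adl_bands = "B", group = "PB"),
        list(adl_bands = "A", iadl = "some", group = "PA2"),
        list(adl_bands = "A", iadl = "none", group = "PA1")
      )
    )
  )
  class(config) <- "rug_rule_config"
  validate_rule_config(config)
}

#' Validate a classification rule configuration
#'
#' Checks the structural invariants of the rule table: every category has a
#' trigger, the terminal category's trigger is always true, band cut-points
#' are increasing, and the split map is total — every (ADL band, IADL band,
#' service count) combination reachable in a category resolves to a group of
#' that category.
#'
#' @param config A rule configuration list (see [default_rule_config()]).
#' @return `config`, invisibly classed `rug_rule_config`, if valid;
#'   otherwise a configuration error.
#' @export
validate_rule_config <- function(config) {
  cats <- rug_categories()$category
  grp <- rug_groups()

  for (field in c("adl_scale", "iadl_scale", "category_triggers", "split_map")) {
    if (is.null(config[[field]])) {
      stop_config("rule config is missing field '%s'", field)
    }
  }
  adl <- config$adl_scale
  if (length(adl$items) < 1 || is.null(adl$weights) ||
      !all(adl$items %in% names(adl$weights))) {
    stop_config("adl_scale must name items and give a weight for each item")
  }
  if (length(adl$code_range) != 2 || adl$code_range[1] > adl$code_range[2]) {
    stop_config("adl_scale$code_range must be an increasing pair")
  }
  if (is.unsorted(adl$band_cuts, strictly = TRUE) ||
      length(adl$band_cuts) != 3) {
    stop_config("adl_scale$band_cuts must be three strictly increasing cut-points")
  }
  if (length(config$iadl_scale$items) < 1) {
    stop_config("iadl_scale must name at least one item")
  }

  missing_trig <- setdiff(cats, names(config$category_triggers))
  if (length(missing_trig) > 0) {
    stop_config("category_triggers missing for: %s",
                paste(missing_trig, collapse = ", "))
  }
  if (!identical(config$category_triggers$ReducedPhysicalFunctions$type,
                 "always")) {
    stop_config("ReducedPhysicalFunctions must carry the always-true terminal trigger")
  }

  # Split-map totality: every reachable band combination maps to a group of
  # the right category.
  for (cat in cats) {
    rules <- config$split_map[[cat]]
    if (is.null(rules)) stop_config("split_map missing category '%s'", cat)
    codes <- vapply(rules, function(r) r$group, character(1))
    bad <- setdiff(codes, grp$code[grp$category == cat])
    if (length(bad) > 0) {
      stop_config("split_map for %s maps to foreign group(s): %s",
                  cat, paste(bad, collapse = ", "))
    }
    if (cat == "ExtensiveServices") {
      for (k in 1:3) {
        if (is.na(resolve_split(rules, adl_band = "A", iadl_band = "none",
                                n_services = k))) {
          stop_config("split_map for ExtensiveServices unreachable at %d service(s)", k)
        }
      }
    } else {
      for (band in c("A", "B", "C", "D")) {
        for (ib in c("none", "some")) {
          if (is.na(resolve_split(rules, adl_band = band, iadl_band = ib,
                                  n_services = 0))) {
            stop_config("split_map for %s has no rule for ADL band %s / IADL %s",
                        cat, band, ib)
          }
        }
      }
    }
  }
  class(config) <- "rug_rule_config"
  invisible(config)
}

# First matching split rule wins; NA when nothing matches (a config defect
# that validate_rule_config rules out for reachable combinations).
resolve_split <- function(rules, adl_band, iadl_band, n_services) {
  for (r in rules) {
    if (!is.null(r$min_services) && n_services < r$min_services) next
    if (!is.null(r$adl_bands) && !(adl_band %in% r$adl_bands)) next
    if (!is.null(r$iadl) && !identical(iadl_band, r$iadl)) next
    return(r$group)
  }
  NA_character_
}

#' Read or write a rule configuration as YAML
#'
#' @param path File path of the YAML rule configuration.
#' @param config A validated rule configuration.
#' @return `read_rule_config()` returns a validated `rug_rule_config`;
#'   `write_rule_config()` returns `path` invisibly.
#' @export
read_rule_config <- function(path) {
  if (!file.exists(path)) stop_config("rule config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  # yaml returns sequences as lists; flatten the fields the grouper indexes
  # with as atomic vectors
  raw$adl_scale$items <- unlist(raw$adl_scale$items)
  raw$adl_scale$weights <- unlist(raw$adl_scale$weights)
  raw$adl_scale$code_range <- unlist(raw$adl_scale$code_range)
  raw$adl_scale$band_cuts <- unlist(raw$adl_scale$band_cuts)
  raw$iadl_scale$items <- unlist(raw$iadl_scale$items)
  raw$iadl_scale$code_range <- unlist(raw$iadl_scale$code_range)
  raw$category_triggers <- lapply(raw$category_triggers, function(t) {
    if (!is.null(t$flags)) t$flags <- unlist(t$flags)
    t
  })
  raw$split_map <- lapply(raw$split_map, function(rules) {
    lapply(rules, function(r) {
      if (!is.null(r$adl_bands)) r$adl_bands <- unlist(r$adl_bands)
      r
    })
  })
  validate_rule_config(raw)
  structure(raw, class = "rug_rule_config")
}

#' @rdname read_rule_config
#' @export
write_rule_config <- function(config, path) {
  validate_rule_config(config)
  out <- unclass(config)
  out$adl_scale$weights <- as.list(out$adl_scale$weights)
  out$adl_scale$band_cuts <- as.list(out$adl_scale$band_cuts)
  yaml::write_yaml(out, path)
  invisible(path)
}
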