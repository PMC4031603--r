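# Clinical instruments of the foot-function assessment: MNSI totals, ABC
# balance-confidence score, manual muscle-function grades, 30-second
# repetition functional tests, and the trial eligibility screen.

FUNCTIONAL_LEVELS <- c("not_functional", "barely_functional",
                       "reasonably_functional", "functional")

MUSCLES <- c("triceps_surae", "tibialis_anterior", "interosseous",
             "lumbrical", "flexor_hallucis_brevis", "flexor_digitorum_brevis",
             "extensor_hallucis", "extensor_digitorum")

FUNCTIONAL_MOVEMENTS <- c("ankle_flexion", "ankle_extension",
                          "toes_flexion", "toes_extension")

#' Classify a 30-second repetition functional test
#'
#' Maps the repetition count of a foot/ankle movement performed as fast as
#' possible for 30 seconds onto the ordinal functional scale:
#' 0 repetitions not functional, 1-4 barely functional, 5-9 reasonably
#' functional, 10-15 functional. Counts above 15 (possible in a timed
#' trial) are classed functional as a documented extension of the scale.
#'
#' @param repetitions Non-negative integer count(s).
#' @return Ordered factor over the four functional levels.
#' @export
classify_functional_test <- function(repetitions) {
  if (any(is.na(repetitions)) || any(repetitions < 0)) {
    stop("repetitions must be non-negative")
  }
  lab <- cut(repetitions, breaks = c(-0.5, 0.5, 4.5, 9.5, Inf),
             labels = FUNCTIONAL_LEVELS)
  factor(lab, levels = FUNCTIONAL_LEVELS, ordered = TRUE)
}

#' Screen a candidate profile against the trial eligibility criteria
#'
#' Eligibility requires: age 45-65 years, BMI 18.5-29.9 kg/m^2, diabetes
#' diagnosed for at least 7 years, MNSI questionnaire score above 2 (of
#' 13), MNSI physical score above 1 (of 10) with impaired vibration
#' perception, independent walking, and none of the exclusion conditions
#' (plantar ulceration history, amputation, other neurological or
#' orthopedic impairment, major vascular complication, severe retinopathy
#' or nephropathy, ongoing physiotherapy or offloading devices). All failed
#' criteria are reported, not only the first.
#'
#' @param profile Named list with required fields `age`, `bmi`,
#'   `diabetes_duration` (years), `mnsi_questionnaire`, `mnsi_physical`,
#'   `impaired_vibration` (logical); optional logical exclusion flags
#'   `ulceration_history`, `amputation`, `other_impairment`,
#'   `vascular_complication`, `severe_retinopathy`, `severe_nephropathy`,
#'   `ongoing_physiotherapy` (default `FALSE`) and `walks_independently`
#'   (default `TRUE`).
#' @return List with `eligible` (logical) and `reasons` (character vector
#'   of all failed criteria; empty when eligible).
#' @export
check_eligibility <- function(profile) {
  required <- c("age", "bmi", "diabetes_duration", "mnsi_questionnaire",
                "mnsi_physical", "impaired_vibration")
  missing <- setdiff(required, names(profile))
  if (length(missing)) {
    stop("incomplete profile, missing field(s): ",
         paste(missing, collapse = ", "))
  }
  flag <- function(name, default = FALSE) {
    v <- profile[[name]]
    if (is.null(v)) default else isTRUE(v)
  }
  reasons <- character(0)
  if (profile$age < 45 || profile$age > 65) {
    reasons <- c(reasons, "age out of 45-65 years")
  }
  if (profile$bmi < 18.5 || profile$bmi > 29.9) {
    reasons <- c(reasons, "BMI out of 18.5-29.9 kg/m^2")
  }
  if (profile$diabetes_duration < 7) {
    reasons <- c(reasons, "diabetes diagnosed for less than 7 years")
  }
  if (profile$mnsi_questionnaire <= 2) {
    reasons <- c(reasons, "MNSI questionnaire score not above 2")
  }
  if (profile$mnsi_physical <= 1) {
    reasons <- c(reasons, "MNSI physical score not above 1")
  }
  if (!isTRUE(profile$impaired_vibration)) {
    reasons <- c(reasons, "no impaired vibration perception")
  }
  if (!flag("walks_independently", TRUE)) {
    reasons <- c(reasons, "cannot walk independently")
  }
  exclusions <- c(
    ulceration_history = "history of plantar ulceration",
    amputation = "partial or total foot amputation",
    other_impairment = "other neurological or orthopedic impairment",
    vascular_complication = "major vascular complication",
    severe_retinopathy = "severe retinopathy",
    severe_nephropathy = "severe nephropathy",
    ongoing_physiotherapy = "receiving physiotherapy or offloading devices"
  )
  for (nm in names(exclusions)) {
    if (flag(nm)) reasons <- c(reasons, unname(exclusions[nm]))
  }
  list(eligible = length(reasons) == 0, reasons = reasons)
}

#' Validate a clinical record's score ranges
#'
#' Checks every stored score against its instrument range: MNSI
#' questionnaire 0-13; MNSI physical 0-10 in 0.5 steps; ABC 0-100%; manual
#' muscle grades integers 0-5; functional repetition counts non-negative.
#' Returns all violations; an empty result means the record is valid.
#'
#' @param record Named list with any of `mnsi_questionnaire`,
#'   `mnsi_physical`, `abc`, `muscle_grades` (named numeric vector),
#'   `functional_repetitions` (named numeric vector).
#' @return Character vector of violations (empty if valid).
#' @export
validate_clinical_record <- function(record) {
  v <- character(0)
  chk_range <- function(x, lo, hi, what) {
    if (is.null(x)) return(character(0))
    bad <- which(is.na(x) | x < lo | x > hi)
    if (length(bad)) {
      sprintf("%s value %s outside %g-%g", what,
              paste(x[bad], collapse = ", "), lo, hi)
    } else {
      character(0)
    }
  }
  v <- c(v, chk_range(record$mnsi_questionnaire, 0, 13, "MNSI questionnaire"))
  v <- c(v, chk_range(record$mnsi_physical, 0, 10, "MNSI physical"))
  if (!is.null(record$mnsi_physical) &&
      any(abs(record$mnsi_physical * 2 - round(record$mnsi_physical * 2)) > 1e-9)) {
    v <- c(v, "MNSI physical score must be in 0.5 steps")
  }
  v <- c(v, chk_range(record$abc, 0, 100, "ABC"))
  mg <- record$muscle_grades
  if (!is.null(mg)) {
    v <- c(v, chk_range(mg, 0, 5, "muscle grade"))
    if (any(!is.na(mg) & mg != round(mg))) {
      v <- c(v, "muscle grades must be whole numbers on the 0-5 scale")
    }
  }
  fr <- record$functional_repetitions
  if (!is.null(fr) && any(is.na(fr) | fr < 0)) {
    v <- c(v, "functional repetition counts must be non-negative")
  }
  v
}
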