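#' Eligibility exclusion reasons, in their fixed reporting order
#' @export
EXCLUSION_REASONS <- c("age_lt_18", "not_emergent_icu", "icu_days_lt_3",
                       "hospital_los_lt_5", "missing_bi", "missing_bmi",
                       "missing_age", "no_crp_within_7_days")

#' Apply the study eligibility rules to one admission
#'
#' An admission is included iff: age >= 18 years, emergent ICU admission,
#' at least 3 consecutive ICU days, at least 5 hospital days, Barthel index
#' at discharge, BMI and age all recorded, and at least one CRP measurement
#' within the first 7 hospital days. Every failing rule is recorded (the
#' check never short-circuits), so an attrition report can count all
#' reasons. An absent field becomes its missing-data exclusion reason,
#' never an error.
#'
#' @param record a one-row data frame (or list) with the cohort schema.
#' @return a list with `included` (logical) and `exclusion_reasons`
#'   (character vector in the fixed order of [EXCLUSION_REASONS]).
#' @export
apply_eligibility <- function(record) {
  reasons <- character(0)
  age <- record$age
  if (is.null(age) || is.na(age)) {
    reasons <- c(reasons, "missing_age")
  } else if (age < 18) {
    reasons <- c(reasons, "age_lt_18")
  }
  if (is.null(record$emergent_icu) || is.na(record$emergent_icu) ||
      !record$emergent_icu)
    reasons <- c(reasons, "not_emergent_icu")
  if (is.null(record$icu_consecutive_days) ||
      is.na(record$icu_consecutive_days) || record$icu_consecutive_days < 3)
    reasons <- c(reasons, "icu_days_lt_3")
  if (is.null(record$hospital_los_days) || is.na(record$hospital_los_days) ||
      record$hospital_los_days < 5)
    reasons <- c(reasons, "hospital_los_lt_5")
  if (is.null(record$barthel_index) || is.na(record$barthel_index))
    reasons <- c(reasons, "missing_bi")
  if (is.null(record$bmi) || is.na(record$bmi))
    reasons <- c(reasons, "missing_bmi")
  crp <- unlist(record[paste0("crp_day", 0:6)], use.names = FALSE)
  if (all(is.na(crp)))
    reasons <- c(reasons, "no_crp_within_7_days")
  reasons <- EXCLUSION_REASONS[EXCLUSION_REASONS %in% reasons]
  list(included = length(reasons) == 0L, exclusion_reasons = reasons)
}

#' Filter a cohort and report attrition
#'
#' Applies [apply_eligibility()] to every admission and returns the included
#' cohort (with a `diagnosis_category` column added) together with a
#' flowchart-style attrition table. Included plus excluded always equals the
#' input count, and an excluded admission contributes to every reason it
#' fails.
#'
#' @param cohort a cohort data frame ([cohort_columns()] schema).
#' @return a list with `included` (data frame), `attrition` (data frame of
#'   reason/count, plus `n_input`, `n_included`, `n_excluded` rows), and
#'   `excluded_idx` (row indices that were dropped).
#' @export
build_cohort <- function(cohort) {
  # vectorised transcription of apply_eligibility() (kept in lockstep by a
  # property test)
  crp <- as.matrix(cohort[, paste0("crp_day", 0:6)])
  fails <- cbind(
    age_lt_18 = !is.na(cohort$age) & cohort$age < 18,
    not_emergent_icu = is.na(cohort$emergent_icu) | !cohort$emergent_icu,
    icu_days_lt_3 = is.na(cohort$icu_consecutive_days) |
      cohort$icu_consecutive_days < 3,
    hospital_los_lt_5 = is.na(cohort$hospital_los_days) |
      cohort$hospital_los_days < 5,
    missing_bi = is.na(cohort$barthel_index),
    missing_bmi = is.na(cohort$bmi),
    missing_age = is.na(cohort$age),
    no_crp_within_7_days = rowSums(!is.na(crp)) == 0)
  fails <- fails[, EXCLUSION_REASONS, drop = FALSE]
  included <- unname(rowSums(fails) == 0)
  reason_counts <- unname(colSums(fails))
  attrition <- data.frame(
    item = c("n_input", EXCLUSION_REASONS, "n_excluded", "n_included"),
    count = c(nrow(cohort), reason_counts, sum(!included), sum(included)),
    stringsAsFactors = FALSE)
  inc <- cohort[included, , drop = FALSE]
  if (nrow(inc))
    inc$diagnosis_category <- mapply(categorize_diagnosis, inc$icd10,
                                     inc$has_sepsis_code, USE.NAMES = FALSE)
  list(included = inc, attrition = attrition,
       excluded_idx = which(!included))
}

#' Assign an admission-diagnosis category from ICD-10 codes
#'
#' Maps the admission diagnosis to one of the eight categories. A recorded
#' sepsis code always wins. Otherwise the first code in record order
#' decides, with the narrower neurology range (I60-I69, plus all of G)
#' taking precedence over the broader cardiovascular range (I00-I99):
#' cardiovascular I00-99; pulmonary J; metabolic E; neurology I60-69 and
#' G00-99; trauma S00-99, T00-19, T33-88, V, W, X, Y00-09; digestive
#' K20-93; anything else is `others`. Matching uses the three-character
#' category prefix.
#'
#' @param icd10_codes character vector of ICD-10 codes (a single string may
#'   hold several codes separated by `;`).
#' @param has_sepsis_code logical; TRUE if the admission carries a sepsis
#'   diagnosis code.
#' @return one of [DIAGNOSIS_CATEGORIES].
#' @examples
#' categorize_diagnosis("I63.9", FALSE)  # neurology
#' categorize_diagnosis("I21.9", TRUE)   # sepsis
#' @export
categorize_diagnosis <- function(icd10_codes, has_sepsis_code) {
  if (isTRUE(has_sepsis_code)) return("sepsis")
  codes <- unlist(strsplit(as.character(icd10_codes), ";"), use.names = FALSE)
  codes <- trimws(codes)
  codes <- codes[nzchar(codes)]
  if (length(codes) == 0L) return("others")
  for (code in codes) {
    if (!grepl("^[A-Z][0-9]{2}", code))
      stop("malformed ICD-10 code: '", code, "'", call. = FALSE)
  }
  categorize_one_code(codes[[1]])
}

categorize_one_code <- function(code) {
  letter <- substr(code, 1, 1)
  num <- as.integer(substr(code, 2, 3))
  if ((letter == "I" && num >= 60 && num <= 69) || letter == "G")
    return("neurology")
  if (letter == "I") return("cardiovascular")
  if (letter == "J") return("pulmonary")
  if (letter == "E") return("metabolic")
  if (letter == "S" || letter %in% c("V", "W", "X") ||
      (letter == "T" && (num <= 19 || (num >= 33 && num <= 88))) ||
      (letter == "Y" && num <= 9))
    return("trauma")
  if (letter == "K" && num >= 20 && num <= 93) return("digestive")
  "others"
}
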