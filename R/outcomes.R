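#' Four-group GLIM labels
#' @export
FOUR_GROUPS <- c("crp_pos_bmi_pos", "crp_pos_bmi_neg",
                 "crp_neg_bmi_pos", "crp_neg_bmi_neg")

#' Derive primary and secondary outcomes for one admission
#'
#' The primary composite is in-hospital death OR Barthel index < 60 at
#' discharge (strict) OR hospital length of stay >= 14 days. Secondary
#' outcomes are death by day 14, death by day 28, and BI and LOS as
#' continuous values.
#'
#' @param record one-row data frame or list with `died_in_hospital`,
#'   `death_day`, `barthel_index`, `hospital_los_days`.
#' @return a list of outcome flags and values.
#' @export
derive_outcomes <- function(record) {
  bi <- record$barthel_index
  los <- record$hospital_los_days
  died <- record$died_in_hospital
  if (is.null(bi) || is.na(bi) || is.null(los) || is.na(los) ||
      is.null(died) || is.na(died))
    stop("cannot derive outcomes: BI, LOS and death status must be present",
         call. = FALSE)
  death_day <- record$death_day
  dbk <- function(k) isTRUE(died) && !is.null(death_day) &&
    !is.na(death_day) && death_day <= k
  bi_lt_60 <- bi < 60
  los_ge_14 <- los >= 14
  list(in_hospital_death = isTRUE(died),
       bi_lt_60 = bi_lt_60,
       los_ge_14 = los_ge_14,
       composite = isTRUE(died) || bi_lt_60 || los_ge_14,
       death_by_day14 = dbk(14), death_by_day28 = dbk(28),
       bi = bi, los = los)
}

#' GLIM low-BMI phenotypic criterion (Asian thresholds)
#'
#' Low BMI is defined age-dependently: BMI < 18.5 kg/m^2 under 70 years,
#' BMI < 20 kg/m^2 at 70 years or older. Both comparisons are strict.
#'
#' @param bmi body mass index, kg/m^2 (> 0).
#' @param age age in years.
#' @return logical (vectorised).
#' @examples
#' low_bmi_flag(18.4, 69)  # TRUE
#' low_bmi_flag(19.9, 70)  # TRUE
#' @export
low_bmi_flag <- function(bmi, age) {
  (age < 70 & bmi < 18.5) | (age >= 70 & bmi < 20)
}

#' Four-group GLIM classification
#'
#' Combines the inflammation criterion (maximum CRP over days 0-2 strictly
#' above the cut-off -> CRP+) with the low-BMI criterion (-> BMI+) into one
#' of four mutually exclusive groups.
#'
#' @param low_bmi logical low-BMI flag (vectorised).
#' @param crp_max_d02 maximum CRP over days 0-2, mg/dL.
#' @param cutoff CRP cut-off, mg/dL (> 0).
#' @return character vector with values in [FOUR_GROUPS].
#' @export
four_group <- function(low_bmi, crp_max_d02, cutoff) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1, cutoff > 0)
  crp_pos <- crp_max_d02 > cutoff
  ifelse(crp_pos,
         ifelse(low_bmi, "crp_pos_bmi_pos", "crp_pos_bmi_neg"),
         ifelse(low_bmi, "crp_neg_bmi_pos", "crp_neg_bmi_neg"))
}

#' Add outcome-flag columns to a cohort
#'
#' Appends the primary and secondary outcome flags and the GLIM low-BMI
#' flag; [add_four_group()] then assigns the four-group label once a CRP
#' cut-off is known.
#'
#' @param cohort cohort data frame with BI, LOS and death columns.
#' @return the cohort with outcome flag columns and `low_bmi`.
#' @export
add_outcome_flags <- function(cohort) {
  # vectorised transcription of derive_outcomes() (kept in lockstep by a test)
  if (anyNA(cohort$barthel_index) || anyNA(cohort$hospital_los_days) ||
      anyNA(cohort$died_in_hospital))
    stop("cannot derive outcomes: BI, LOS and death status must be present",
         call. = FALSE)
  died <- cohort$died_in_hospital
  cohort$in_hospital_death <- died
  cohort$bi_lt_60 <- cohort$barthel_index < 60
  cohort$los_ge_14 <- cohort$hospital_los_days >= 14
  cohort$composite <- died | cohort$bi_lt_60 | cohort$los_ge_14
  dd <- cohort$death_day
  cohort$death_by_day14 <- died & !is.na(dd) & dd <= 14
  cohort$death_by_day28 <- died & !is.na(dd) & dd <= 28
  cohort$low_bmi <- low_bmi_flag(cohort$bmi, cohort$age)
  cohort
}

#' Assign the four-group GLIM label
#'
#' @param cohort cohort with `low_bmi` and `crp_max_d02` columns.
#' @param cutoff CRP cut-off (mg/dL) for the inflammation criterion.
#' @return the cohort with a `four_group` column.
#' @export
add_four_group <- function(cohort, cutoff) {
  cohort$four_group <- four_group(cohort$low_bmi, cohort$crp_max_d02, cutoff)
  cohort
}

#' Percentage of a count, as printed in clinical tables
#'
#' One decimal place of `100 * count / n`, the arithmetic used for every
#' "n (%)" cell in the report tables.
#'
#' @param count event count.
#' @param n group size.
#' @return numeric percentage rounded to one decimal.
#' @export
pct <- function(count, n) round(100 * count / n, 1)
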