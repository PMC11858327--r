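#' Respiratory SOFA component from the level of respiratory support
#'
#' Claims databases record interventions but not PaO2/FiO2, so the
#' respiratory component is scored from the highest level of respiratory
#' support on days 0-1: no oxygen therapy 0, oxygen 1, NPPV or high-flow
#' nasal cannula 2, invasive mechanical ventilation 3, ECMO 4.
#'
#' @param support one of [OXYGEN_LEVELS].
#' @return integer score 0-4.
#' @export
respiratory_sofa <- function(support) {
  idx <- match(support, OXYGEN_LEVELS)
  if (any(is.na(idx)))
    stop("unknown oxygen support level: '",
         paste(support[is.na(idx)], collapse = "', '"), "'", call. = FALSE)
  idx - 1L
}

#' Cardiovascular SOFA component from day-1 catecholamine doses
#'
#' Patients on no catecholamines score 0 regardless of blood pressure
#' (mean arterial pressure is ignored in this claims-based modification).
#' Non-zero doses use the standard SOFA bands: dopamine <= 5 or any
#' dobutamine scores 2; dopamine > 5 or noradrenaline/adrenaline <= 0.1
#' scores 3; dopamine > 15 or noradrenaline/adrenaline > 0.1 scores 4. All
#' doses in ug/kg/min (day-1 means).
#'
#' @param dopamine,dobutamine,noradrenaline,adrenaline doses >= 0.
#' @param map_mmhg optional mean arterial pressure; accepted and ignored.
#' @return integer score 0-4.
#' @export
cardiovascular_sofa <- function(dopamine = 0, dobutamine = 0,
                                noradrenaline = 0, adrenaline = 0,
                                map_mmhg = NULL) {
  doses <- c(dopamine = dopamine, dobutamine = dobutamine,
             noradrenaline = noradrenaline, adrenaline = adrenaline)
  if (any(is.na(doses)) || any(doses < 0))
    stop("catecholamine doses must be non-negative", call. = FALSE)
  if (all(doses == 0)) return(0L)
  na_ad <- max(noradrenaline, adrenaline)
  if (dopamine > 15 || na_ad > 0.1) return(4L)
  if (dopamine > 5 || na_ad > 0) return(3L)
  2L
}

#' Catecholamine index
#'
#' Summary vasoactive load on day 1, in ug/kg/min equivalents:
#' dopamine + dobutamine + 100 x noradrenaline + 100 x adrenaline.
#'
#' @inheritParams cardiovascular_sofa
#' @return numeric index >= 0.
#' @examples
#' catecholamine_index(dobutamine = 3, noradrenaline = 0.05)  # 8
#' @export
catecholamine_index <- function(dopamine = 0, dobutamine = 0,
                                noradrenaline = 0, adrenaline = 0) {
  doses <- c(dopamine, dobutamine, noradrenaline, adrenaline)
  if (any(is.na(doses)) || any(doses < 0))
    stop("catecholamine doses must be non-negative", call. = FALSE)
  dopamine + dobutamine + 100 * noradrenaline + 100 * adrenaline
}

#' Total modified SOFA score for one admission
#'
#' Respiratory and cardiovascular components are computed from the recorded
#' interventions ([respiratory_sofa()], [cardiovascular_sofa()]); the
#' laboratory-based components (coagulation, liver, renal, CNS) are taken
#' from the record's precomputed subscores.
#'
#' @param record a one-row data frame or list with `oxygen_support`,
#'   the four catecholamine dose columns, and `sofa_coag`, `sofa_liver`,
#'   `sofa_renal`, `sofa_cns`.
#' @return a list of the six components and `total` (0-24).
#' @export
total_sofa <- function(record) {
  for (comp in c("sofa_coag", "sofa_liver", "sofa_renal", "sofa_cns")) {
    if (is.null(record[[comp]]) || is.na(record[[comp]]))
      stop("missing SOFA subscore: ", comp, call. = FALSE)
  }
  resp <- respiratory_sofa(record$oxygen_support)
  cardio <- cardiovascular_sofa(
    dopamine = record$dopamine %||% 0, dobutamine = record$dobutamine %||% 0,
    noradrenaline = record$noradrenaline %||% 0,
    adrenaline = record$adrenaline %||% 0)
  comps <- c(respiratory = resp, cardiovascular = cardio,
             coagulation = record$sofa_coag, liver = record$sofa_liver,
             renal = record$sofa_renal, cns = record$sofa_cns)
  c(as.list(comps), list(total = sum(comps)))
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Add SOFA and catecholamine-index columns to a cohort
#'
#' @param cohort cohort data frame with intervention and subscore columns.
#' @return the cohort with `sofa_total` and `catecholamine_index` appended.
#' @export
add_severity <- function(cohort) {
  # vectorised transcription of total_sofa() (kept in lockstep by a test)
  for (comp in c("sofa_coag", "sofa_liver", "sofa_renal", "sofa_cns"))
    if (anyNA(cohort[[comp]]))
      stop("missing SOFA subscore: ", comp, call. = FALSE)
  resp <- match(cohort$oxygen_support, OXYGEN_LEVELS) - 1L
  if (anyNA(resp)) stop("unknown oxygen support level", call. = FALSE)
  na_ad <- pmax(cohort$noradrenaline, cohort$adrenaline)
  any_dose <- cohort$dopamine + cohort$dobutamine + na_ad > 0
  cardio <- ifelse(!any_dose, 0L,
            ifelse(cohort$dopamine > 15 | na_ad > 0.1, 4L,
            ifelse(cohort$dopamine > 5 | na_ad > 0, 3L, 2L)))
  cohort$sofa_total <- resp + cardio + cohort$sofa_coag +
    cohort$sofa_liver + cohort$sofa_renal + cohort$sofa_cns
  cohort$catecholamine_index <- catecholamine_index(
    cohort$dopamine, cohort$dobutamine, cohort$noradrenaline,
    cohort$adrenaline)
  cohort
}
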