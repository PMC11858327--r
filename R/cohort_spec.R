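#' Diagnosis categories used throughout the package
#'
#' The eight admission-diagnosis categories, in their fixed order.
#' @export
DIAGNOSIS_CATEGORIES <- c("sepsis", "cardiovascular", "pulmonary", "metabolic",
                          "neurology", "trauma", "digestive", "others")

#' Oxygen-support levels, from none to ECMO
#' @export
OXYGEN_LEVELS <- c("none", "oxygen", "nppv_or_hfnc",
                   "mechanical_ventilation", "ecmo")

#' Construct a synthetic-cohort specification
#'
#' A `cohort_spec` describes one synthetic ICU claims cohort: how many
#' admissions, the admission-diagnosis mix, per-category CRP trajectory
#' kinetics, CRP measurement missingness, logistic outcome models driven by
#' the (uncensored) maximum CRP over days 0-2, demographic distributions,
#' and intervention rates. The defaults emulate a large Japanese ICU claims
#' cohort: mean age about 73 years, roughly 59% male, mean BMI 22.5 kg/m^2,
#' a neurology-heavy diagnosis mix, CRP peaking around hospital day 1.5
#' (about 36 h after insult), and measurement missingness leaving roughly a
#' third of patients with CRP observed on every one of days 0-2.
#'
#' @param n_patients number of admissions to simulate (>= 1).
#' @param seed integer RNG seed; the same spec always yields the same cohort.
#' @param diagnosis_mix named probability vector over the eight categories in
#'   [DIAGNOSIS_CATEGORIES]; must sum to 1.
#' @param crp_kinetics data frame with one row per category and columns
#'   `category`, `log_mean` (log-scale day-0 CRP mean, log mg/dL), `log_sd`
#'   (patient-level log-scale SD), `rise` (log-scale rise from day 0 to the
#'   peak), `peak_day` (day of the CRP peak), `decay` (log-scale decline per
#'   day after the peak).
#' @param day_noise_sd log-scale SD of the independent day-to-day
#'   measurement noise around each patient's trajectory.
#' @param missingness_prob probability a CRP measurement is absent, either a
#'   scalar or a vector of length 7 (days 0-6); all values in [0, 1].
#' @param outcome_model named list with elements `death`, `bi_lt_60`, and
#'   `los_ge_14`, each a numeric vector with named components `intercept`,
#'   `beta_maxcrp` (per mg/dL of true max CRP days 0-2), `beta_lowbmi`
#'   (GLIM low-BMI flag), and `beta_age` (per decade of age over 70), on the
#'   logit scale.
#' @param age_dist,bmi_dist numeric `c(mean, sd)` of the (truncated) normal
#'   age and BMI distributions.
#' @param sex_ratio probability an admission is male.
#' @param intervention_rates named list: `oxygen_support` (base probabilities
#'   over [OXYGEN_LEVELS]), `chdf`, `ihd`, `iabp` (probabilities), and
#'   `catecholamine` (named list of per-drug use probabilities `p_*` and
#'   log-normal dose parameters). A single severity link `sev_link` tilts all
#'   intervention probabilities with the patient's log max CRP so that
#'   high-CRP patients are sicker, as in real ICU cohorts.
#' @param ineligible_frac fraction of records deliberately violating one
#'   eligibility rule (minors, short ICU/hospital stays, missing Barthel
#'   index or BMI, no CRP at all, non-emergent admission), so that
#'   downstream filtering is exercised.
#'
#' @return an object of class `cohort_spec`.
#' @seealso [simulate_cohort()], [planted_truth()]
#' @export
cohort_spec <- function(n_patients = 1000L,
                        seed = 1L,
                        diagnosis_mix = default_diagnosis_mix(),
                        crp_kinetics = default_crp_kinetics(),
                        day_noise_sd = 0.35,
                        missingness_prob = c(0.15, 0.38, 0.38, 0.45, 0.45, 0.5, 0.5),
                        outcome_model = default_outcome_model(),
                        age_dist = c(mean = 73, sd = 14.5),
                        bmi_dist = c(mean = 22.5, sd = 4.6),
                        sex_ratio = 0.588,
                        intervention_rates = default_intervention_rates(),
                        ineligible_frac = 0.05) {
  spec <- structure(
    list(n_patients = n_patients, seed = seed, diagnosis_mix = diagnosis_mix,
         crp_kinetics = crp_kinetics, day_noise_sd = day_noise_sd,
         missingness_prob = missingness_prob, outcome_model = outcome_model,
         age_dist = age_dist, bmi_dist = bmi_dist, sex_ratio = sex_ratio,
         intervention_rates = intervention_rates,
         ineligible_frac = ineligible_frac),
    class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat("  n_patients:", x$n_patients, "  seed:", x$seed, "\n")
  cat("  diagnosis mix:",
      paste(sprintf("%s=%.3f", names(x$diagnosis_mix), x$diagnosis_mix),
            collapse = " "), "\n")
  cat("  missingness (days 0-6):",
      paste(format(x$missingness_prob, digits = 2), collapse = " "), "\n")
  cat("  ineligible fraction:", x$ineligible_frac, "\n")
  invisible(x)
}

#' Default generator parameters
#'
#' The study conditions the synthetic cohort emulates:
#' `default_diagnosis_mix()` gives the admission-diagnosis fractions of a
#' representative large ICU claims cohort; `default_crp_kinetics()` the
#' per-category CRP trajectory parameters (log-scale day-0 baseline, rise to
#' a peak at about day 1.5 since CRP peaks roughly 36 h after insult, then
#' slow decay; sepsis and digestive admissions present with high CRP on day
#' 0, neurology low); `default_outcome_model()` the logit-scale outcome
#' coefficients (covariates: true max CRP days 0-2 in mg/dL, GLIM low-BMI
#' flag, age in decades over 70); `default_intervention_rates()` the base
#' intervention probabilities and catecholamine dose distributions.
#'
#' @return the corresponding parameter object (see [cohort_spec()]).
#' @name cohort_defaults
NULL

#' @rdname cohort_defaults
#' @export
default_diagnosis_mix <- function() {
  c(sepsis = 0.114, cardiovascular = 0.246, pulmonary = 0.064,
    metabolic = 0.020, neurology = 0.275, trauma = 0.075,
    digestive = 0.049, others = 0.157)
}

#' @rdname cohort_defaults
#' @export
default_crp_kinetics <- function() {
  data.frame(
    category = DIAGNOSIS_CATEGORIES,
    log_mean = c(2.1, 0.0, 1.4, 0.0, -0.9, 0.4, 1.6, 0.2),
    log_sd   = c(0.9, 1.0, 0.9, 1.0, 1.0, 0.9, 0.9, 1.0),
    rise     = c(0.8, 1.4, 0.8, 0.8, 0.9, 1.2, 0.9, 1.0),
    peak_day = rep(1.5, 8),
    decay    = c(0.15, 0.2, 0.15, 0.2, 0.1, 0.15, 0.15, 0.2),
    stringsAsFactors = FALSE)
}

#' @rdname cohort_defaults
#' @export
default_outcome_model <- function() {
  list(
    death     = c(intercept = -2.60, beta_maxcrp = 0.050,
                  beta_lowbmi = 0.60, beta_age = 0.20),
    bi_lt_60  = c(intercept = -0.60, beta_maxcrp = 0.050,
                  beta_lowbmi = 0.80, beta_age = 0.30),
    los_ge_14 = c(intercept = 0.90, beta_maxcrp = 0.040,
                  beta_lowbmi = 0.20, beta_age = 0.10))
}

#' @rdname cohort_defaults
#' @export
default_intervention_rates <- function() {
  list(
    oxygen_support = c(none = 0.318, oxygen = 0.30, nppv_or_hfnc = 0.09,
                       mechanical_ventilation = 0.258, ecmo = 0.034),
    chdf = 0.034, ihd = 0.029, iabp = 0.040,
    catecholamine = list(
      p_dopamine = 0.05, dopamine_meanlog = log(4), dopamine_sdlog = 0.6,
      p_dobutamine = 0.08, dobutamine_meanlog = log(3), dobutamine_sdlog = 0.5,
      p_noradrenaline = 0.25, noradrenaline_meanlog = log(0.1),
      noradrenaline_sdlog = 0.7,
      p_adrenaline = 0.02, adrenaline_meanlog = log(0.05),
      adrenaline_sdlog = 0.7),
    sev_link = 0.4)
}

validate_cohort_spec <- function(spec) {
  stop_field <- function(field, msg)
    stop(sprintf("invalid cohort_spec: field '%s' %s", field, msg),
         call. = FALSE)
  if (!is.numeric(spec$n_patients) || length(spec$n_patients) != 1 ||
      is.na(spec$n_patients) || spec$n_patients < 1)
    stop_field("n_patients", "must be a single count >= 1")
  if (!is.numeric(spec$seed) || length(spec$seed) != 1 || is.na(spec$seed))
    stop_field("seed", "must be a single integer")
  mix <- spec$diagnosis_mix
  if (!is.numeric(mix) || length(mix) != 8 ||
      !setequal(names(mix), DIAGNOSIS_CATEGORIES))
    stop_field("diagnosis_mix",
               "must be a named probability vector over the 8 categories")
  if (any(mix < 0 | mix > 1))
    stop_field("diagnosis_mix", "has probabilities outside [0,1]")
  if (abs(sum(mix) - 1) > 1e-9)
    stop_field("diagnosis_mix", "must sum to 1 (within 1e-9)")
  kin <- spec$crp_kinetics
  need <- c("category", "log_mean", "log_sd", "rise", "peak_day", "decay")
  if (!is.data.frame(kin) || !all(need %in% names(kin)) ||
      !setequal(kin$category, DIAGNOSIS_CATEGORIES))
    stop_field("crp_kinetics",
               "must be a data frame with one row per category")
  if (any(kin$log_sd < 0) || any(kin$peak_day < 0) || any(kin$decay < 0))
    stop_field("crp_kinetics", "has negative sd/peak_day/decay")
  mp <- spec$missingness_prob
  if (!is.numeric(mp) || !(length(mp) %in% c(1L, 7L)) ||
      any(is.na(mp)) || any(mp < 0 | mp > 1))
    stop_field("missingness_prob",
               "must be a scalar or length-7 vector of probabilities in [0,1]")
  om <- spec$outcome_model
  if (!is.list(om) || !setequal(names(om), c("death", "bi_lt_60", "los_ge_14")))
    stop_field("outcome_model",
               "must be a list with elements death, bi_lt_60, los_ge_14")
  for (nm in names(om)) {
    cf <- om[[nm]]
    if (!is.numeric(cf) || !all(c("intercept", "beta_maxcrp", "beta_lowbmi",
                                  "beta_age") %in% names(cf)))
      stop_field(paste0("outcome_model$", nm),
                 "must have intercept, beta_maxcrp, beta_lowbmi, beta_age")
  }
  for (fld in c("age_dist", "bmi_dist")) {
    d <- spec[[fld]]
    if (!is.numeric(d) || length(d) != 2 || d[2] <= 0)
      stop_field(fld, "must be c(mean, sd) with sd > 0")
  }
  if (!is.numeric(spec$sex_ratio) || spec$sex_ratio < 0 || spec$sex_ratio > 1)
    stop_field("sex_ratio", "must be a probability in [0,1]")
  ir <- spec$intervention_rates
  ox <- ir$oxygen_support
  if (!is.numeric(ox) || !setequal(names(ox), OXYGEN_LEVELS) ||
      any(ox < 0) || abs(sum(ox) - 1) > 1e-9)
    stop_field("intervention_rates$oxygen_support",
               "must be probabilities over the five support levels summing to 1")
  for (nm in c("chdf", "ihd", "iabp")) {
    p <- ir[[nm]]
    if (!is.numeric(p) || p < 0 || p > 1)
      stop_field(paste0("intervention_rates$", nm),
                 "must be a probability in [0,1]")
  }
  if (!is.numeric(spec$ineligible_frac) || spec$ineligible_frac < 0 ||
      spec$ineligible_frac > 1)
    stop_field("ineligible_frac", "must be a probability in [0,1]")
  invisible(spec)
}
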