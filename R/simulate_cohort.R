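#' Simulate a DPC-style ICU claims cohort
#'
#' Generates one admission-level table with the statistical structure the
#' downstream analysis assumes: a per-category CRP trajectory on hospital
#' days 0-6 (log-normal baseline, rise to a peak near day 1.5, then decay),
#' per-day measurement missingness, interventions and SOFA lab subscores
#' tilted toward high-CRP patients, and outcomes (in-hospital death,
#' discharge Barthel index < 60, length of stay >= 14 days) drawn from
#' logistic models in the patient's true, pre-censoring maximum CRP over
#' days 0-2, GLIM low-BMI flag, and age. A configurable fraction of records
#' violates one eligibility rule so cohort filtering can be exercised.
#'
#' The generator is fully deterministic given the spec (which includes its
#' seed) and leaves the caller's RNG state untouched.
#'
#' @param spec a [cohort_spec()].
#' @return a data frame with one row per admission. CRP values are in
#'   columns `crp_day0` ... `crp_day6` (NA = not measured). The planted
#'   generation truth is attached as attribute `"truth"` (see
#'   [planted_truth()]).
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_patients = 50, seed = 42))
#' head(cohort$crp_day0)
#' @export
simulate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  sim <- with_cohort_rng(spec$seed, simulate_cohort_impl(spec))
  structure(sim$cohort, truth = sim$truth)
}

#' Planted generation truth for a cohort spec
#'
#' Returns the exact outcome-model coefficients and the per-patient
#' uncensored maximum CRP over days 0-2 (plus the low-BMI flag and age)
#' that [simulate_cohort()] used, for parameter-recovery and planted-effect
#' tests. Regenerating from the same spec gives identical values.
#'
#' @param spec a [cohort_spec()].
#' @return a list with `coefficients` (the spec's outcome models),
#'   `max_crp_d02`, `low_bmi`, `age`, and the drawn outcome flags.
#' @export
planted_truth <- function(spec) {
  validate_cohort_spec(spec)
  with_cohort_rng(spec$seed, simulate_cohort_impl(spec))$truth
}

# Run expr with a private Mersenne-Twister stream, restoring the caller's
# RNG state afterwards.
with_cohort_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

rtnorm <- function(n, mean, sd, lower, upper) {
  pmin(pmax(stats::rnorm(n, mean, sd), lower), upper)
}

# Tilt a base probability on the logit scale by a severity score z.
tilt_prob <- function(p, z, link) stats::plogis(stats::qlogis(p) + link * z)

simulate_cohort_impl <- function(spec) {
  n <- as.integer(spec$n_patients)
  categories <- sample(DIAGNOSIS_CATEGORIES, n, replace = TRUE,
                       prob = spec$diagnosis_mix[DIAGNOSIS_CATEGORIES])

  age <- round(rtnorm(n, spec$age_dist[1], spec$age_dist[2], 18, 105))
  sex <- ifelse(stats::runif(n) < spec$sex_ratio, "male", "female")
  bmi <- round(rtnorm(n, spec$bmi_dist[1], spec$bmi_dist[2], 10, 60), 1)

  # --- CRP trajectories (true values, days 0-6) ---------------------------
  kin <- spec$crp_kinetics
  rownames(kin) <- kin$category
  k <- kin[categories, ]
  baseline <- stats::rnorm(n, k$log_mean, k$log_sd)
  days <- 0:6
  true_crp <- matrix(NA_real_, n, 7)
  for (j in seq_along(days)) {
    t <- days[j]
    m <- ifelse(t <= k$peak_day,
                baseline + k$rise * t / k$peak_day,
                baseline + k$rise - k$decay * (t - k$peak_day))
    true_crp[, j] <- round(exp(m + stats::rnorm(n, 0, spec$day_noise_sd)), 2)
  }
  true_max_d02 <- apply(true_crp[, 1:3, drop = FALSE], 1, max)

  # --- outcomes from the planted logistic models --------------------------
  low_bmi <- (age < 70 & bmi < 18.5) | (age >= 70 & bmi < 20)
  age_dec <- (age - 70) / 10
  draw_outcome <- function(cf) {
    lp <- cf[["intercept"]] + cf[["beta_maxcrp"]] * true_max_d02 +
      cf[["beta_lowbmi"]] * low_bmi + cf[["beta_age"]] * age_dec
    stats::runif(n) < stats::plogis(lp)
  }
  died <- draw_outcome(spec$outcome_model$death)
  bi_low <- draw_outcome(spec$outcome_model$bi_lt_60)
  los_long <- draw_outcome(spec$outcome_model$los_ge_14)

  # LOS / ICU days / death day consistent with the drawn flags
  los <- ifelse(los_long,
                14L + stats::rnbinom(n, size = 2, mu = 12),
                5L + as.integer(floor(stats::runif(n) * 9)))  # 5..13
  icu_days <- pmin(3L + stats::rgeom(n, 0.4), los)
  death_day <- rep(NA_integer_, n)
  death_day[died] <- pmin(1L + stats::rgeom(sum(died), 0.07), los[died])

  # Barthel index: 0-100 in steps of 5 from a latent normal, consistent
  # with the drawn BI<60 flag.
  bi_latent <- ifelse(bi_low, rtnorm(n, 25, 22, 0, 55), rtnorm(n, 85, 15, 60, 100))
  barthel <- as.integer(pmin(pmax(round(bi_latent / 5) * 5, 0), 100))

  # --- interventions, severity-linked -------------------------------------
  ir <- spec$intervention_rates
  z <- as.numeric(scale(log(pmax(true_max_d02, 0.01))))
  ox_base <- ir$oxygen_support[OXYGEN_LEVELS]
  oxygen_support <- vapply(seq_len(n), function(i) {
    w <- ox_base * exp(ir$sev_link * (seq_along(ox_base) - 1) * z[i])
    sample(OXYGEN_LEVELS, 1, prob = w / sum(w))
  }, character(1))
  chdf <- stats::runif(n) < tilt_prob(ir$chdf, z, ir$sev_link)
  ihd  <- stats::runif(n) < tilt_prob(ir$ihd, z, ir$sev_link)
  iabp <- stats::runif(n) < tilt_prob(ir$iabp, z, ir$sev_link)
  cat_par <- ir$catecholamine
  draw_dose <- function(p, meanlog, sdlog) {
    on <- stats::runif(n) < tilt_prob(p, z, ir$sev_link)
    ifelse(on, round(stats::rlnorm(n, meanlog, sdlog), 3), 0)
  }
  dopamine <- draw_dose(cat_par$p_dopamine, cat_par$dopamine_meanlog,
                        cat_par$dopamine_sdlog)
  dobutamine <- draw_dose(cat_par$p_dobutamine, cat_par$dobutamine_meanlog,
                          cat_par$dobutamine_sdlog)
  noradrenaline <- draw_dose(cat_par$p_noradrenaline,
                             cat_par$noradrenaline_meanlog,
                             cat_par$noradrenaline_sdlog)
  adrenaline <- draw_dose(cat_par$p_adrenaline, cat_par$adrenaline_meanlog,
                          cat_par$adrenaline_sdlog)

  # lab-based SOFA subscores, skewed toward 0 and tilted by severity
  sub_probs <- c(0.60, 0.20, 0.10, 0.07, 0.03)
  draw_subscore <- function() {
    vapply(seq_len(n), function(i) {
      w <- sub_probs * exp(0.3 * (0:4) * z[i])
      sample(0:4, 1, prob = w / sum(w))
    }, numeric(1))
  }
  sofa_coag <- draw_subscore(); sofa_liver <- draw_subscore()
  sofa_renal <- draw_subscore(); sofa_cns <- draw_subscore()

  # --- ICD-10 code per category -------------------------------------------
  code_pool <- list(
    sepsis = c("A41.9", "A40.3"), cardiovascular = c("I21.9", "I50.0", "I71.0"),
    pulmonary = c("J18.9", "J96.0"), metabolic = c("E11.1", "E87.2"),
    neurology = c("I63.9", "I61.9", "G41.9"), trauma = c("S06.5", "T07"),
    digestive = c("K65.0", "K92.2"), others = c("N17.9", "R57.1", "C34.9"))
  icd10 <- vapply(categories, function(ct) sample(code_pool[[ct]], 1),
                  character(1))
  has_sepsis_code <- categories == "sepsis"

  # --- CRP measurement censoring ------------------------------------------
  mp <- spec$missingness_prob
  if (length(mp) == 1L) mp <- rep(mp, 7)
  obs_crp <- true_crp
  for (j in 1:7) obs_crp[stats::runif(n) < mp[j], j] <- NA_real_

  emergent_icu <- rep(TRUE, n)
  barthel_out <- barthel
  bmi_out <- bmi

  # --- planted eligibility violations --------------------------------------
  n_bad <- round(spec$ineligible_frac * n)
  if (n_bad > 0) {
    bad_idx <- sample.int(n, n_bad)
    kinds <- sample(c("minor", "short_icu", "short_los", "no_bi", "no_bmi",
                      "no_crp", "not_emergent"), n_bad, replace = TRUE)
    for (i in seq_len(n_bad)) {
      r <- bad_idx[i]
      switch(kinds[i],
        minor = { age[r] <- sample(16:17, 1) },
        short_icu = { icu_days[r] <- sample(1:2, 1) },
        short_los = {
          los[r] <- sample(3:4, 1)
          icu_days[r] <- min(icu_days[r], los[r])
          if (!is.na(death_day[r])) death_day[r] <- min(death_day[r], los[r])
        },
        no_bi = { barthel_out[r] <- NA_integer_ },
        no_bmi = { bmi_out[r] <- NA_real_ },
        no_crp = { obs_crp[r, ] <- NA_real_ },
        not_emergent = { emergent_icu[r] <- FALSE })
    }
  }

  cohort <- data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    age = age, sex = sex, bmi = bmi_out,
    icd10 = icd10, has_sepsis_code = has_sepsis_code,
    emergent_icu = emergent_icu,
    icu_consecutive_days = icu_days, hospital_los_days = los,
    died_in_hospital = died, death_day = death_day,
    barthel_index = barthel_out,
    stringsAsFactors = FALSE)
  for (j in 1:7) cohort[[paste0("crp_day", j - 1)]] <- obs_crp[, j]
  cohort$oxygen_support <- oxygen_support
  cohort$chdf <- chdf; cohort$ihd <- ihd; cohort$iabp <- iabp
  cohort$dopamine <- dopamine; cohort$dobutamine <- dobutamine
  cohort$noradrenaline <- noradrenaline; cohort$adrenaline <- adrenaline
  cohort$sofa_coag <- sofa_coag; cohort$sofa_liver <- sofa_liver
  cohort$sofa_renal <- sofa_renal; cohort$sofa_cns <- sofa_cns

  truth <- list(coefficients = spec$outcome_model,
                max_crp_d02 = true_max_d02,
                low_bmi = low_bmi, age = age,
                died = died, bi_lt_60 = bi_low, los_ge_14 = los_long)
  list(cohort = cohort, truth = truth)
}

#' Expected columns of a cohort CSV
#'
#' Column names of the admission-level table written and read by this
#' package (the synthetic-generator schema).
#' @return character vector of column names.
#' @export
cohort_columns <- function() {
  c("patient_id", "age", "sex", "bmi", "icd10", "has_sepsis_code",
    "emergent_icu", "icu_consecutive_days", "hospital_los_days",
    "died_in_hospital", "death_day", "barthel_index",
    paste0("crp_day", 0:6), "oxygen_support", "chdf", "ihd", "iabp",
    "dopamine", "dobutamine", "noradrenaline", "adrenaline",
    "sofa_coag", "sofa_liver", "sofa_renal", "sofa_cns")
}

#' Write / read a cohort CSV
#'
#' One row per admission, CRP as columns `crp_day0` ... `crp_day6` with an
#' empty cell for a missing measurement.
#'
#' @param cohort a cohort data frame.
#' @param path file path.
#' @return `read_cohort_csv` returns the cohort data frame; on a schema
#'   mismatch it raises an error listing the missing and unexpected columns.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort[, cohort_columns()], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  missing_cols <- setdiff(cohort_columns(), names(df))
  extra_cols <- setdiff(names(df), cohort_columns())
  if (length(missing_cols) || length(extra_cols))
    stop("cohort CSV schema mismatch; missing: [",
         paste(missing_cols, collapse = ", "), "]; unexpected: [",
         paste(extra_cols, collapse = ", "), "]", call. = FALSE)
  for (col in c("has_sepsis_code", "emergent_icu", "died_in_hospital",
                "chdf", "ihd", "iabp"))
    df[[col]] <- as.logical(df[[col]])
  df
}
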