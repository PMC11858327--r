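test_that("identical spec and seed give identical cohorts", {
  spec <- cohort_spec(n_patients = 100, seed = 1)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a, b)
  # and the caller's RNG stream is untouched
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(simulate_cohort(spec)); after <- runif(3)
  expect_identical(before, after)
})

test_that("zero missingness yields CRP on every day 0-6", {
  spec <- cohort_spec(n_patients = 200, seed = 2, missingness_prob = 0,
                      ineligible_frac = 0)
  co <- simulate_cohort(spec)
  crp <- as.matrix(co[, paste0("crp_day", 0:6)])
  expect_false(anyNA(crp))
})

test_that("invalid specs are rejected with the offending field named", {
  expect_error(cohort_spec(n_patients = 0), "n_patients")
  expect_error(cohort_spec(missingness_prob = 1.2), "missingness_prob")
  expect_error(cohort_spec(sex_ratio = -0.1), "sex_ratio")
  expect_error(cohort_spec(diagnosis_mix = c(sepsis = 1)), "diagnosis_mix")
  bad_mix <- stats::setNames(rep(0.2, 8), DIAGNOSIS_CATEGORIES)
  expect_error(cohort_spec(diagnosis_mix = bad_mix), "sum to 1")
})

test_that("generated records satisfy their structural invariants", {
  co <- simulate_cohort(cohort_spec(n_patients = 2000, seed = 3))
  ok_bi <- is.na(co$barthel_index) | co$barthel_index %in% seq(0, 100, 5)
  expect_true(all(ok_bi))
  expect_true(all(is.na(co$bmi) | co$bmi > 0))
  dd <- co$death_day
  expect_true(all(is.na(dd) | dd <= co$hospital_los_days))
  expect_true(all(is.na(dd) == !co$died_in_hospital))
  expect_true(all(co$dopamine >= 0 & co$dobutamine >= 0 &
                    co$noradrenaline >= 0 & co$adrenaline >= 0))
  expect_true(all(co$icu_consecutive_days <= co$hospital_los_days))
  expect_true(all(co$oxygen_support %in% OXYGEN_LEVELS))
})

test_that("planted truth passes through the spec coefficients", {
  spec <- cohort_spec(n_patients = 50, seed = 4)
  truth <- planted_truth(spec)
  expect_identical(truth$coefficients, spec$outcome_model)
  # same spec, different seed: same coefficients, different patient draws
  spec2 <- spec; spec2$seed <- 5L
  truth2 <- planted_truth(spec2)
  expect_identical(truth2$coefficients, truth$coefficients)
  expect_false(identical(truth2$max_crp_d02, truth$max_crp_d02))
  # truth matches what simulate_cohort attaches
  expect_identical(attr(simulate_cohort(spec), "truth"), truth)
})

test_that("with all betas zero, outcome rates match the intercepts", {
  p <- c(death = 0.12, bi = 0.5, los = 0.75)
  spec <- null_spec(20000, seed = 11, p_death = p[1], p_bi = p[2],
                    p_los = p[3])
  truth <- planted_truth(spec)
  n <- spec$n_patients
  for (pair in list(c("died", 1), c("bi_lt_60", 2), c("los_ge_14", 3))) {
    rate <- mean(truth[[pair[1]]])
    p0 <- as.numeric(p[as.integer(pair[2])])
    se <- sqrt(p0 * (1 - p0) / n)
    expect_lt(abs(rate - p0), 3 * se)
  }
})

test_that("mortality rises monotonically across planted max-CRP quartiles", {
  om <- default_outcome_model()
  om$death["beta_maxcrp"] <- 0.15   # a clearly positive planted effect
  spec <- cohort_spec(n_patients = 20000, seed = 12, outcome_model = om,
                      ineligible_frac = 0)
  truth <- planted_truth(spec)
  q <- cut(truth$max_crp_d02,
           breaks = stats::quantile(truth$max_crp_d02, probs = 0:4 / 4),
           include.lowest = TRUE, labels = FALSE)
  rates <- tapply(truth$died, q, mean)
  expect_true(all(diff(rates) > 0))
})

test_that("stronger planted CRP effects give higher downstream AUC", {
  aucs <- vapply(c(0, 0.05, 0.15), function(beta) {
    om <- default_outcome_model()
    for (nm in names(om)) om[[nm]]["beta_maxcrp"] <- beta
    spec <- cohort_spec(n_patients = 20000, seed = 13, outcome_model = om,
                        ineligible_frac = 0)
    truth <- planted_truth(spec)
    composite <- truth$died | truth$bi_lt_60 | truth$los_ge_14
    roc_auc(build_roc(truth$max_crp_d02, composite))
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
})

test_that("cohort CSV round-trips and rejects schema mismatches", {
  co <- simulate_cohort(cohort_spec(n_patients = 30, seed = 6))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  back <- read_cohort_csv(path)
  expect_equal(back$crp_day0, co$crp_day0)
  expect_identical(back$died_in_hospital, co$died_in_hospital)
  bad <- utils::read.csv(path)
  bad$age <- NULL
  bad$rogue <- 1
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, path2, row.names = FALSE)
  expect_error(read_cohort_csv(path2), "age.*rogue|missing")
})
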