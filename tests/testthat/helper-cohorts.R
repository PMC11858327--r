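# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a mid-sized analysed cohort shared across test files
analyzed_cohort <- function() {
  cached("analyzed", {
    spec <- cohort_spec(n_patients = 4000, seed = 101)
    run_pipeline(run_config(input = spec))
  })
}

# spec with all outcome betas zero: outcomes independent of CRP/BMI/age
null_spec <- function(n, seed, p_death = 0.12, p_bi = 0.5, p_los = 0.75) {
  null_cf <- function(p) c(intercept = unname(stats::qlogis(p)),
                           beta_maxcrp = 0, beta_lowbmi = 0, beta_age = 0)
  om <- list(death = null_cf(p_death), bi_lt_60 = null_cf(p_bi),
             los_ge_14 = null_cf(p_los))
  cohort_spec(n_patients = n, seed = seed, outcome_model = om,
              ineligible_frac = 0)
}

# a fully eligible single record for eligibility tests
eligible_record <- function(...) {
  rec <- list(age = 70, sex = "male", bmi = 22, icd10 = "I63.9",
              has_sepsis_code = FALSE, emergent_icu = TRUE,
              icu_consecutive_days = 4, hospital_los_days = 10,
              died_in_hospital = FALSE, death_day = NA_integer_,
              barthel_index = 80L,
              crp_day0 = 2, crp_day1 = 3, crp_day2 = 4, crp_day3 = NA,
              crp_day4 = NA, crp_day5 = NA, crp_day6 = NA)
  mods <- list(...)
  rec[names(mods)] <- mods
  rec
}

# random small ROC instance (ties included) for property tests
random_roc_instance <- function() {
  n <- sample(4:50, 1)
  scores <- round(stats::runif(n, 0, 10), sample(0:2, 1))  # induces ties
  labels <- stats::runif(n) < 0.5
  if (!any(labels)) labels[sample.int(n, 1)] <- TRUE
  if (all(labels)) labels[sample.int(n, 1)] <- FALSE
  list(scores = scores, labels = labels)
}

# independent pair-counting AUC oracle: P(score_pos > score_neg) + 0.5 ties
auc_pair_count <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# brute-force Youden maximiser over observed thresholds with >= positivity
youden_brute_force <- function(scores, labels) {
  thr <- sort(unique(scores))
  j <- vapply(thr, function(t) {
    sens <- sum(scores >= t & labels) / sum(labels)
    spec <- sum(scores < t & !labels) / sum(!labels)
    sens + spec - 1
  }, numeric(1))
  best <- max(j)
  list(cutoff = min(thr[j >= best - 1e-12]), j = best)
}

# independently coded Conover-Iman p-values (formula written from the
# definition: pooled mid-ranks, tie-corrected pooled variance, H-corrected
# variance factor, two-sided t with N - k df)
conover_oracle <- function(samples) {
  k <- length(samples)
  x <- unlist(samples)
  g <- rep(seq_len(k), lengths(samples))
  N <- length(x)
  rk <- rank(x)
  Rbar <- vapply(seq_len(k), function(i) mean(rk[g == i]), numeric(1))
  n_i <- lengths(samples)
  H <- stats::kruskal.test(x, factor(g))$statistic
  S2 <- (sum(rk^2) - N * (N + 1)^2 / 4) / (N - 1)
  p <- matrix(NA_real_, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(S2 * (N - 1 - H) / (N - k) * (1 / n_i[i] + 1 / n_i[j]))
    tij <- (Rbar[i] - Rbar[j]) / se
    p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tij), N - k)
  }
  p
}
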