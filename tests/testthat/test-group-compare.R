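test_that("Kruskal-Wallis H matches the closed form on tie-free data", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  # H = 12/(N(N+1)) * sum n_i (Rbar_i - (N+1)/2)^2 with N = 6
  expect_equal(kw$h, 12 / (6 * 7) * (3 * (2 - 3.5)^2 + 3 * (5 - 3.5)^2),
               tolerance = 1e-12)
  expect_equal(round(kw$h, 3), 3.857)
  expect_equal(kw$df, 1)
})

test_that("identical groups give H = 0 and p = 1; binary data are accepted", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(kw$h, 0)
  expect_equal(kw$p, 1)
  kwb <- kruskal_wallis(list(c(0, 0, 1, 1), c(1, 1, 1, 0), c(0, 0, 0, 1)))
  expect_true(is.finite(kwb$h) && kwb$p >= 0 && kwb$p <= 1)
  expect_error(kruskal_wallis(list(numeric(0), 1:3)), "non-empty")
  expect_error(kruskal_wallis(list(1:3)), "two groups")
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(71)
  g <- list(rnorm(8), rnorm(10, 1), rnorm(6, -1))
  h0 <- kruskal_wallis(g)$h
  expect_equal(kruskal_wallis(lapply(g, exp))$h, h0, tolerance = 1e-12)
  expect_equal(kruskal_wallis(lapply(g, function(x) x^3))$h, h0,
               tolerance = 1e-12)
})

test_that("k = 2 Kruskal-Wallis matches the Mann-Whitney normal approximation", {
  set.seed(72)
  x <- rnorm(15); y <- rnorm(12, 0.8)
  kw <- kruskal_wallis(list(x, y))
  w <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(kw$p, w$p.value, tolerance = 1e-6)
})

test_that("Conover pairwise p-values match the independent oracle", {
  set.seed(73)
  for (i in 1:20) {
    k <- sample(3:5, 1)
    samples <- lapply(seq_len(k),
                      function(j) round(rnorm(sample(5:12, 1), j / 2), 1))
    cv <- conover_pairwise(samples)
    oracle <- conover_oracle(samples)
    expect_equal(unname(cv$p_raw), unname(oracle), tolerance = 1e-10)
    expect_true(isSymmetric(cv$p_raw))
    expect_true(all(cv$p_adjusted >= cv$p_raw - 1e-15, na.rm = TRUE))
    expect_true(all(cv$p_raw >= 0 & cv$p_raw <= 1, na.rm = TRUE))
  }
})

test_that("well separated groups are all pairwise significant", {
  cv <- conover_pairwise(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  off <- cv$p_raw[upper.tri(cv$p_raw)]
  expect_true(all(off < 0.05))
})

test_that("two identical groups among k have pairwise p near 1", {
  cv <- conover_pairwise(list(c(1, 5, 9, 13), c(1, 5, 9, 13),
                              c(20, 21, 22, 23)))
  expect_gt(cv$p_raw[1, 2], 0.999)
})

test_that("Conover p is monotone in the rank-mean separation", {
  base <- list(1:6, 7:12, 25:30)
  closer <- list(1:6, 4:9, 25:30)   # group 2 pulled toward group 1
  p_far <- conover_pairwise(base)$p_raw[1, 2]
  p_near <- conover_pairwise(closer)$p_raw[1, 2]
  expect_lt(p_far, p_near)
})

test_that("null Kruskal-Wallis p-values are approximately uniform", {
  set.seed(74)
  pvals <- replicate(200, {
    kruskal_wallis(split(rnorm(48), rep(1:4, each = 12)))$p
  })
  # rank statistics are discrete, so p-values can repeat across replicates
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("compare_four_groups returns eight comparisons with Table-3-style summaries", {
  res <- analyzed_cohort()
  cmp <- res$comparisons
  expect_length(cmp, 8)
  expect_setequal(names(cmp),
                  c("in_hospital_death", "bi_lt_60", "los_ge_14", "composite",
                    "death_by_day14", "death_by_day28", "bi", "los"))
  for (c1 in cmp) {
    expect_s3_class(c1, "group_comparison")
    expect_false(c1$undefined)
    expect_true(c1$kw_h >= 0)
    expect_true(c1$kw_p >= 0 && c1$kw_p <= 1)
    ns <- vapply(c1$group_summaries, `[[`, numeric(1), "n")
    expect_equal(sum(ns), nrow(res$cohort))
  }
  # binary summaries carry count/pct, continuous carry median/IQR
  expect_true(all(c("count", "pct") %in%
                    names(cmp$in_hospital_death$group_summaries[[1]])))
  expect_true(all(c("median", "iqr") %in% names(cmp$bi$group_summaries[[1]])))
  # an empty group marks tests undefined rather than crashing
  co <- res$cohort
  co$four_group[co$four_group == "crp_neg_bmi_pos"] <- "crp_neg_bmi_neg"
  cmp2 <- compare_four_groups(co)
  expect_true(all(vapply(cmp2, `[[`, logical(1), "undefined")))
})
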