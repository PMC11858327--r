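test_that("build_roc enumerates thresholds with >= positivity", {
  r <- build_roc(c(0.1, 0.4, 0.35, 0.8), c(FALSE, FALSE, TRUE, TRUE))
  expect_identical(r$thresholds, c(Inf, 0.8, 0.4, 0.35, 0.1))
  expect_equal(r$sensitivity, c(0, 0.5, 0.5, 1, 1))
  expect_equal(r$specificity, c(1, 1, 0.5, 0.5, 0))
  expect_equal(r$n_pos, 2)
  expect_equal(r$n_neg, 2)
  expect_error(build_roc(1:4, rep(TRUE, 4)), "degenerate")
})

test_that("perfect separation and constant scores behave as expected", {
  r <- build_roc(c(1, 2, 10, 11), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(roc_auc(r), 1)
  yo <- youden_optimal(r)
  expect_equal(yo$optimal_cutoff, 10)  # smallest positive's score
  expect_equal(yo$youden_j, 1)

  rc <- build_roc(rep(2, 5), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_identical(rc$thresholds, c(Inf, 2))
  expect_equal(rc$sensitivity[2], 1)
  expect_equal(rc$specificity[2], 0)
  expect_equal(youden_optimal(rc)$youden_j, 0)
})

test_that("AUC equals the hand-derived value on the worked example", {
  r <- build_roc(c(0.1, 0.4, 0.35, 0.8), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(roc_auc(r), 0.75)  # 3 of 4 pos/neg pairs concordant
  yo <- youden_optimal(r)
  expect_equal(yo$optimal_cutoff, 0.35)  # J tie with 0.8 broken low
  expect_equal(yo$youden_j, 0.5)
})

test_that("trapezoidal AUC equals pair counting with half ties (200 cases)", {
  set.seed(61)
  for (i in 1:200) {
    inst <- random_roc_instance()
    a1 <- roc_auc(build_roc(inst$scores, inst$labels))
    a2 <- auc_pair_count(inst$scores, inst$labels)
    expect_equal(a1, a2, tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(62)
  for (i in 1:20) {
    inst <- random_roc_instance()
    ours <- roc_auc(build_roc(inst$scores, inst$labels))
    ref <- suppressMessages(as.numeric(
      pROC::auc(pROC::roc(inst$labels, inst$scores, direction = "<"))))
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("youden_optimal agrees with brute force and never picks the sentinel", {
  set.seed(63)
  for (i in 1:200) {
    inst <- random_roc_instance()
    yo <- youden_optimal(build_roc(inst$scores, inst$labels))
    bf <- youden_brute_force(inst$scores, inst$labels)
    expect_equal(yo$optimal_cutoff, bf$cutoff)
    expect_equal(yo$youden_j, bf$j, tolerance = 1e-12)
    expect_true(is.finite(yo$optimal_cutoff))
    expect_equal(yo$youden_j, yo$sens_at_cutoff + yo$spec_at_cutoff - 1,
                 tolerance = 1e-12)
  }
})

test_that("label flips mirror the AUC as expected", {
  set.seed(64)
  for (i in 1:50) {
    inst <- random_roc_instance()
    a <- roc_auc(build_roc(inst$scores, inst$labels))
    a_neg <- roc_auc(build_roc(-inst$scores, !inst$labels))
    expect_equal(a, a_neg, tolerance = 1e-12)
    a_flip <- roc_auc(build_roc(inst$scores, !inst$labels))
    expect_equal(a_flip, 1 - a, tolerance = 1e-12)
  }
})

test_that("sens_spec_at counts the confusion table at a fixed cut-off", {
  s <- c(1, 2, 3, 4); l <- c(FALSE, FALSE, TRUE, TRUE)
  expect_equal(sens_spec_at(s, l, 0), c(sens = 1, spec = 0))
  expect_equal(sens_spec_at(s, l, 100), c(sens = 0, spec = 1))
  # direct count: strict calls only 3,4 positive (spec 2/2); non-strict also
  # calls the negative score 2 positive (spec 1/2)
  expect_equal(sens_spec_at(s, l, 2, strict = TRUE), c(sens = 1, spec = 1))
  expect_equal(sens_spec_at(s, l, 2, strict = FALSE), c(sens = 1, spec = 0.5))
  expect_error(sens_spec_at(s, rep(TRUE, 4), 2), "degenerate")
})

test_that("windowed subgroup analysis yields 54 rows with one cut-off per row-group", {
  res <- analyzed_cohort()
  tab <- res$table1
  expect_equal(nrow(tab), 54)
  expect_equal(nrow(unique(tab[, c("population", "subgroup", "window")])), 54)
  # optimal cut-off reported only once per population x subgroup
  per_group <- tapply(!is.na(tab$optimal_cutoff),
                      paste(tab$population, tab$subgroup), sum)
  defined <- tapply(!is.na(tab$auc), paste(tab$population, tab$subgroup), sum)
  expect_true(all(per_group[defined > 0] == 1))
  expect_true(all(per_group[defined == 0] == 0))
  # the cut-off sits on the window with the highest AUC
  for (key in names(per_group[defined > 0])) {
    rows <- tab[paste(tab$population, tab$subgroup) == key, ]
    best <- rows$window[which.max(rows$auc)]
    expect_identical(rows$window[!is.na(rows$optimal_cutoff)], best)
  }
})

test_that("a subgroup with one outcome class is undefined, not an error", {
  res <- analyzed_cohort()
  co <- res$cohort
  co$composite[co$diagnosis_category == "metabolic"] <- TRUE
  tab <- windowed_subgroup_analysis(co)
  met <- tab[tab$subgroup == "metabolic" & tab$population == "all_case", ]
  expect_true(all(is.na(met$auc)))
})
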