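#' Build an ROC curve for a score against a binary outcome
#'
#' Sweeps the distinct observed score values in descending order, calling a
#' patient positive when `score >= threshold`, plus a sentinel threshold
#' above the maximum giving the (sensitivity, specificity) = (0, 1) corner.
#' Tied scores are counted together at their shared threshold.
#'
#' @param scores numeric vector (finite).
#' @param labels logical vector, TRUE = event.
#' @return an object of class `roc_curve`: list with `thresholds`
#'   (descending, first element the sentinel `Inf`), `sensitivity`,
#'   `specificity`, `n_pos`, `n_neg`.
#' @examples
#' r <- build_roc(c(0.1, 0.4, 0.35, 0.8), c(FALSE, FALSE, TRUE, TRUE))
#' roc_auc(r)
#' @export
build_roc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (!all(is.finite(scores))) stop("scores must be finite", call. = FALSE)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("degenerate outcome: need at least one positive and one negative",
         call. = FALSE)
  # one pass over scores sorted descending; tied scores share a threshold
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  block_end <- cumsum(rle(s)$lengths)
  thr <- s[block_end]
  cum_pos <- cumsum(l); cum_neg <- cumsum(!l)
  sens <- cum_pos[block_end] / n_pos          # positives with score >= thr
  spec <- (n_neg - cum_neg[block_end]) / n_neg  # negatives with score < thr
  structure(list(thresholds = c(Inf, thr),
                 sensitivity = c(0, sens),
                 specificity = c(1, spec),
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("<roc_curve> ", length(x$thresholds) - 1L, " thresholds, ",
      x$n_pos, " positives / ", x$n_neg, " negatives; AUC = ",
      format(roc_auc(x), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Area under an ROC curve
#'
#' Trapezoidal area over (1 - specificity, sensitivity). Equals the
#' rank/pair-counting form (probability that a random positive outscores a
#' random negative, ties counted one half).
#'
#' @param curve a [build_roc()] object.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(curve) {
  x <- 1 - curve$specificity
  y <- curve$sensitivity
  # curve ends at (1,1) because the smallest observed score calls everyone
  # positive; append explicitly for safety on degenerate curves
  if (x[length(x)] != 1 || y[length(y)] != 1) { x <- c(x, 1); y <- c(y, 1) }
  ord <- order(x, y)
  x <- x[ord]; y <- y[ord]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Youden-optimal cut-off from an ROC curve
#'
#' Selects the observed score value maximising the Youden index
#' J = sensitivity + specificity - 1. Ties are broken toward the smallest
#' cut-off (favouring sensitivity in a screening context); the sentinel
#' threshold is never selected.
#'
#' @param curve a [build_roc()] object.
#' @return a list with `optimal_cutoff`, `youden_j`, `sens_at_cutoff`,
#'   `spec_at_cutoff`, and `auc`.
#' @export
youden_optimal <- function(curve) {
  idx <- seq_along(curve$thresholds)[-1]            # drop the sentinel
  j <- curve$sensitivity[idx] + curve$specificity[idx] - 1
  best_j <- max(j)
  cands <- curve$thresholds[idx][j >= best_j - 1e-12]
  cut <- min(cands)
  at <- which(curve$thresholds == cut)
  list(optimal_cutoff = cut, youden_j = best_j,
       sens_at_cutoff = curve$sensitivity[at],
       spec_at_cutoff = curve$specificity[at],
       auc = roc_auc(curve))
}

#' Sensitivity and specificity at a fixed cut-off
#'
#' @param scores,labels as in [build_roc()].
#' @param cutoff the cut-off value.
#' @param strict if TRUE a positive call is `score > cutoff`, else
#'   `score >= cutoff`.
#' @return named numeric `c(sens, spec)`.
#' @export
sens_spec_at <- function(scores, labels, cutoff, strict = FALSE) {
  labels <- as.logical(labels)
  if (sum(labels) == 0L || sum(!labels) == 0L)
    stop("degenerate outcome: need at least one positive and one negative",
         call. = FALSE)
  call_pos <- if (strict) scores > cutoff else scores >= cutoff
  c(sens = sum(call_pos & labels) / sum(labels),
    spec = sum(!call_pos & !labels) / sum(!labels))
}

#' Windowed, per-diagnosis ROC analysis
#'
#' For each analysis population (all-case: every included admission;
#' complete-case: admissions with CRP measured on each of days 0-2), each
#' CRP window (day 0, max days 0-1, max days 0-2) and each diagnosis
#' subgroup ("all" plus the eight categories), computes the AUC of the CRP
#' statistic against the composite outcome. Within each population x
#' subgroup row, the Youden-optimal cut-off is reported only for the window
#' with the highest AUC, matching how such summary tables are constructed.
#'
#' @param cohort an included cohort with CRP features, outcomes and
#'   `diagnosis_category` columns.
#' @return a data frame with 2 x 3 x 9 = 54 rows: `population`, `subgroup`,
#'   `window`, `n`, `n_pos`, `n_neg`, `auc`, `youden_j`, `optimal_cutoff`
#'   (NA except on each row-group's best window), `sens_at_cutoff`,
#'   `spec_at_cutoff`. Subgroups with a single outcome class (or no
#'   patients) get NA statistics rather than an error.
#' @export
windowed_subgroup_analysis <- function(cohort) {
  windows <- c(day0 = "crp_day0", d01 = "crp_max_d01", d02 = "crp_max_d02")
  pops <- list(all_case = cohort,
               complete_case = cohort[cohort$complete_case, , drop = FALSE])
  rows <- list()
  for (pop in names(pops)) {
    dat <- pops[[pop]]
    for (sub in c("all", DIAGNOSIS_CATEGORIES)) {
      sdat <- if (sub == "all") dat
              else dat[dat$diagnosis_category == sub, , drop = FALSE]
      stats_by_win <- lapply(names(windows), function(w) {
        scores <- sdat[[windows[[w]]]]
        labels <- sdat$composite
        if (nrow(sdat) == 0L || sum(labels) == 0L || sum(!labels) == 0L)
          return(NULL)
        yo <- youden_optimal(build_roc(scores, labels))
        yo
      })
      names(stats_by_win) <- names(windows)
      aucs <- vapply(stats_by_win,
                     function(s) if (is.null(s)) NA_real_ else s$auc,
                     numeric(1))
      best <- if (all(is.na(aucs))) NA_character_
              else names(windows)[which.max(aucs)]
      for (w in names(windows)) {
        s <- stats_by_win[[w]]
        labels <- sdat$composite
        rows[[length(rows) + 1L]] <- data.frame(
          population = pop, subgroup = sub, window = w,
          n = nrow(sdat),
          n_pos = sum(labels), n_neg = sum(!labels),
          auc = if (is.null(s)) NA_real_ else s$auc,
          youden_j = if (is.null(s)) NA_real_ else s$youden_j,
          optimal_cutoff = if (!is.null(s) && identical(w, best))
            s$optimal_cutoff else NA_real_,
          sens_at_cutoff = if (!is.null(s) && identical(w, best))
            s$sens_at_cutoff else NA_real_,
          spec_at_cutoff = if (!is.null(s) && identical(w, best))
            s$spec_at_cutoff else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
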