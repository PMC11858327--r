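#' Kruskal-Wallis omnibus test on a list of samples
#'
#' Rank-based k-group comparison with the usual tie correction, p-value
#' from the chi-square approximation with k - 1 degrees of freedom
#' (delegated to [stats::kruskal.test()]). Works on binary 0/1 outcomes as
#' well, where the mid-rank treatment of ties makes it a valid test of
#' proportion differences.
#'
#' @param samples list of k >= 2 non-empty numeric vectors.
#' @return a list with `h` (the tie-corrected statistic), `p`, `df`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))$h  # 3.857
#' @export
kruskal_wallis <- function(samples) {
  check_samples(samples)
  x <- unlist(samples, use.names = FALSE)
  g <- factor(rep(seq_along(samples), lengths(samples)))
  kt <- stats::kruskal.test(x, g)
  list(h = unname(kt$statistic), p = unname(kt$p.value),
       df = unname(kt$parameter))
}

check_samples <- function(samples) {
  if (!is.list(samples) || length(samples) < 2)
    stop("need a list of at least two groups", call. = FALSE)
  if (any(lengths(samples) == 0))
    stop("every group must be non-empty", call. = FALSE)
  if (sum(lengths(samples)) < 3)
    stop("need at least 3 observations in total", call. = FALSE)
  invisible(samples)
}

#' Conover-Iman pairwise post hoc test
#'
#' All-pairs rank comparison following a Kruskal-Wallis test. Uses pooled
#' mid-ranks, the tie-corrected pooled rank variance
#' S^2 = (sum r^2 - N (N+1)^2 / 4) / (N - 1), and the Kruskal-Wallis-
#' corrected variance factor (N - 1 - H) / (N - k); the statistic for
#' groups i, j is t = (Rbar_i - Rbar_j) / sqrt(S^2 (N-1-H)/(N-k)
#' (1/n_i + 1/n_j)), referred two-sided to a t distribution with N - k
#' degrees of freedom. Raw and Bonferroni-adjusted (x k(k-1)/2, capped at
#' 1) p-value matrices are both returned: the adjustment is deliberately
#' explicit because an all-pairs comparison at alpha = 0.05 without it
#' inflates the family-wise error.
#'
#' @param samples list of k >= 2 non-empty numeric vectors.
#' @return a list with `statistic` (k x k t-statistics), `p_raw`,
#'   `p_adjusted` (symmetric matrices, NA diagonal), `h`, `df`.
#' @export
conover_pairwise <- function(samples) {
  check_samples(samples)
  k <- length(samples)
  n_i <- lengths(samples)
  x <- unlist(samples, use.names = FALSE)
  g <- rep(seq_len(k), n_i)
  N <- length(x)
  if (N <= k)
    stop("need more observations than groups for the t reference",
         call. = FALSE)
  r <- rank(x)                                  # mid-ranks
  rbar <- tapply(r, g, mean)
  s2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  h <- unname(kruskal_wallis(samples)$h)
  vfac <- s2 * max(N - 1 - h, 0) / (N - k)
  tmat <- matrix(NA_real_, k, k)
  praw <- matrix(NA_real_, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se <- sqrt(vfac * (1 / n_i[i] + 1 / n_i[j]))
      tij <- if (se == 0) {
        if (rbar[i] == rbar[j]) 0 else Inf * sign(rbar[i] - rbar[j])
      } else (rbar[i] - rbar[j]) / se
      p <- 2 * stats::pt(-abs(tij), df = N - k)
      tmat[i, j] <- tmat[j, i] <- tij
      praw[i, j] <- praw[j, i] <- p
    }
  }
  padj <- pmin(praw * k * (k - 1) / 2, 1)
  gnames <- names(samples) %||chr% paste0("group", seq_len(k))
  dimnames(tmat) <- dimnames(praw) <- dimnames(padj) <- list(gnames, gnames)
  list(statistic = tmat, p_raw = praw, p_adjusted = padj, h = h, df = N - k)
}

`%||chr%` <- function(a, b) if (is.null(a)) b else a

#' Compare outcomes across the four GLIM groups
#'
#' Runs the Kruskal-Wallis omnibus test and the Conover-Iman post hoc over
#' the four-group classification for each of the eight study outcomes:
#' in-hospital death, BI < 60, LOS >= 14, the composite, 14-day death,
#' 28-day death, and BI and LOS as continuous values. Binary outcomes are
#' tested by the same rank procedure as continuous ones. Group summaries
#' report n (%) for binary outcomes and median (IQR) for continuous ones.
#'
#' @param cohort an included cohort with `four_group` and outcome columns.
#' @return a named list of `group_comparison` objects, each with
#'   `outcome_name`, `type`, `kw_h`, `kw_p`, `pairwise` (raw p matrix),
#'   `adjusted_pairwise`, and `group_summaries`. If any of the four groups
#'   is empty, the tests for every outcome are marked undefined (NA).
#' @export
compare_four_groups <- function(cohort) {
  outcome_defs <- list(
    in_hospital_death = "binary", bi_lt_60 = "binary", los_ge_14 = "binary",
    composite = "binary", death_by_day14 = "binary",
    death_by_day28 = "binary", bi = "continuous", los = "continuous")
  cohort$bi <- cohort$barthel_index
  cohort$los <- cohort$hospital_los_days
  groups <- factor(cohort$four_group, levels = FOUR_GROUPS)
  out <- list()
  for (nm in names(outcome_defs)) {
    type <- outcome_defs[[nm]]
    vals <- as.numeric(cohort[[nm]])
    samples <- split(vals, groups)
    summaries <- lapply(samples, function(v) {
      if (type == "binary")
        list(n = length(v), count = sum(v), pct = pct(sum(v), length(v)))
      else
        list(n = length(v), median = stats::median(v),
             iqr = unname(stats::quantile(v, c(0.25, 0.75))))
    })
    if (any(lengths(samples) == 0)) {
      out[[nm]] <- structure(
        list(outcome_name = nm, type = type, kw_h = NA_real_, kw_p = NA_real_,
             pairwise = NULL, adjusted_pairwise = NULL,
             group_summaries = summaries, undefined = TRUE),
        class = "group_comparison")
      next
    }
    kw <- kruskal_wallis(samples)
    cv <- conover_pairwise(samples)
    out[[nm]] <- structure(
      list(outcome_name = nm, type = type, kw_h = kw$h, kw_p = kw$p,
           pairwise = cv$p_raw, adjusted_pairwise = cv$p_adjusted,
           group_summaries = summaries, undefined = FALSE),
      class = "group_comparison")
  }
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> ", x$outcome_name, " (", x$type, ")\n", sep = "")
  if (isTRUE(x$undefined)) {
    cat("  undefined (empty group)\n")
  } else {
    cat(sprintf("  Kruskal-Wallis H = %.3f, p = %.3g\n", x$kw_h, x$kw_p))
  }
  invisible(x)
}
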