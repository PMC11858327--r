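#' Linearly interpolate missing CRP on days 0-2
#'
#' Retrospective cohorts do not measure CRP every day, so missing values on
#' hospital days 0-2 are filled by linear interpolation between the nearest
#' observed measurements anywhere on days 0-6. A missing day before the
#' first observation (or after the last) takes the nearest observed value
#' (flat carry, the degenerate case of linear interpolation). Observed
#' values are never altered and days 3-6 are left as recorded.
#'
#' @param values numeric vector of length 7: CRP (mg/dL) on days 0-6, NA
#'   where not measured.
#' @return the vector with days 0-2 filled; attribute `"imputed_days"`
#'   records which of days 0, 1, 2 were filled. Errors if no day is
#'   observed at all (such records are excluded upstream).
#' @examples
#' interpolate_crp(c(2, NA, NA, 8, NA, NA, NA))  # days 1-2 -> 4, 6
#' @export
interpolate_crp <- function(values) {
  stopifnot(length(values) == 7)
  obs <- which(!is.na(values))
  if (length(obs) == 0L)
    stop("cannot interpolate a CRP series with no observed values",
         call. = FALSE)
  out <- values
  target <- intersect(1:3, which(is.na(values)))   # days 0-2 (1-based)
  if (length(target)) {
    if (length(obs) == 1L) {
      out[target] <- values[obs]
    } else {
      fill <- stats::approx(x = obs - 1, y = values[obs], xout = target - 1,
                            method = "linear", rule = 2)$y
      out[target] <- fill
    }
  }
  attr(out, "imputed_days") <- target - 1L
  out
}

#' Windowed CRP features for one filled series
#'
#' Computes the three inflammation statistics compared by the analysis:
#' the CRP level on day 0, the highest level over days 0-1, and the highest
#' level over days 0-2, from the interpolated series. A patient is a
#' complete case iff CRP was actually measured (not imputed) on each of
#' days 0, 1 and 2.
#'
#' @param filled a series returned by [interpolate_crp()].
#' @param original the raw series before interpolation (length 7, NA =
#'   not measured).
#' @return a list with `crp_day0`, `crp_max_d01`, `crp_max_d02`,
#'   `complete_case`, and `imputed_days`.
#' @export
crp_features <- function(filled, original) {
  stopifnot(length(original) == 7, all(!is.na(filled[1:3])))
  list(crp_day0 = filled[[1]],
       crp_max_d01 = max(filled[1:2]),
       crp_max_d02 = max(filled[1:3]),
       complete_case = all(!is.na(original[1:3])),
       imputed_days = attr(filled, "imputed_days") %||% integer(0))
}

#' Add CRP feature columns to a cohort
#'
#' Interpolates every admission's CRP series and appends `crp_day0`,
#' `crp_max_d01`, `crp_max_d02`, `complete_case` and `n_imputed_days`
#' columns.
#'
#' @param cohort cohort data frame with `crp_day0` ... `crp_day6` raw
#'   measurement columns.
#' @return the augmented cohort (raw day columns are preserved).
#' @export
add_crp_features <- function(cohort) {
  crp_cols <- paste0("crp_day", 0:6)
  raw <- as.matrix(cohort[, crp_cols])
  feats <- lapply(seq_len(nrow(cohort)), function(i) {
    filled <- interpolate_crp(raw[i, ])
    crp_features(filled, raw[i, ])
  })
  cohort$crp_day0 <- vapply(feats, `[[`, numeric(1), "crp_day0")
  cohort$crp_max_d01 <- vapply(feats, `[[`, numeric(1), "crp_max_d01")
  cohort$crp_max_d02 <- vapply(feats, `[[`, numeric(1), "crp_max_d02")
  cohort$complete_case <- vapply(feats, `[[`, logical(1), "complete_case")
  cohort$n_imputed_days <- vapply(feats, function(f) length(f$imputed_days),
                                  integer(1))
  cohort
}
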