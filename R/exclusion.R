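#' The ten outlier exclusion methods
#'
#' Returns the registry of exclusion rules with their constants. The
#' names are the canonical abbreviations used throughout the package
#' (configuration, CLI, result tables):
#'
#' \describe{
#'   \item{no}{no exclusion.}
#'   \item{cutoff}{a-priori cutoffs: exclude below 200 ms or above
#'     mean + 1000 ms.}
#'   \item{2sd, 3sd}{exclude outside mean +/- k SD (sample SD, n-1).}
#'   \item{tukey1.5}{boxplot fences: outside q0.25 - 1.5 IQR and
#'     q0.75 + 1.5 IQR.}
#'   \item{q10, q05}{fixed quantiles: outside (q0.05, q0.95) resp.
#'     (q0.025, q0.975), excluding about 10% resp. 5% of the data.}
#'   \item{MAD, MAD_adjusted}{outside median +/- 2.5 MAD, with MAD
#'     constant b = 1.4826 (normal theory) or b = 1.1020 (calibrated to
#'     the Ex-Gaussian shape of RT data).}
#'   \item{transform}{square root of range-normalised RTs, z-scored;
#'     exclude |z| > 2.}
#' }
#'
#' All thresholds are computed on the vector the rule is applied to
#' (the observed, possibly contaminated data); comparisons are strict,
#' so values exactly on a threshold are kept.
#'
#' @return A data.frame with columns `method`, `constant` (the
#'   rule-specific multiplier or constant, NA where none applies) and
#'   `description`.
#' @examples
#' exclusion_methods()
#' @export
exclusion_methods <- function() {
  data.frame(
    method = c("no", "cutoff", "2sd", "3sd", "tukey1.5", "q10", "q05",
               "MAD", "MAD_adjusted", "transform"),
    constant = c(NA, NA, 2, 3, 1.5, 0.05, 0.025, 1.4826, 1.1020, 2),
    description = c(
      "no correction for outliers",
      "lower 200 ms, upper mean + 1000 ms",
      "mean +/- 2 SD",
      "mean +/- 3 SD",
      "Tukey fences, 1.5 x IQR beyond the quartiles",
      "outside the 0.05 / 0.95 quantiles",
      "outside the 0.025 / 0.975 quantiles",
      "median +/- 2.5 MAD, b = 1.4826",
      "median +/- 2.5 MAD, b = 1.1020 (Ex-Gaussian adjusted)",
      "z of sqrt range-normalised RTs, |z| > 2"
    ),
    stringsAsFactors = FALSE
  )
}

.method_names <- c("no", "cutoff", "2sd", "3sd", "tukey1.5", "q10", "q05",
                   "MAD", "MAD_adjusted", "transform")

# ---- internal mask functions -------------------------------------------
# Each returns the logical keep mask; degenerate inputs keep everything.
# These are the hot path of the simulation loop: no object construction,
# no warnings (the pipeline counts degenerate events itself).

mask_none <- function(x) rep(TRUE, length(x))

mask_cutoff <- function(x) x >= 200 & x <= mean(x) + 1000

mask_sd <- function(x, k) {
  if (length(x) < 2L) return(rep(TRUE, length(x)))
  m <- mean(x)
  s <- stats::sd(x)
  x >= m - k * s & x <= m + k * s
}

mask_tukey <- function(x, c = 1.5) {
  if (length(x) < 4L) return(rep(TRUE, length(x)))
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2L] - q[1L]
  x >= q[1L] - c * iqr & x <= q[2L] + c * iqr
}

mask_quantile <- function(x, p) {
  q <- stats::quantile(x, c(p, 1 - p), names = FALSE, type = 7)
  x >= q[1L] & x <= q[2L]
}

mask_mad <- function(x, b, k = 2.5) {
  if (length(x) < 2L) return(rep(TRUE, length(x)))
  med <- stats::median(x)
  mad <- b * stats::median(abs(x - med))
  if (mad == 0)
    return(structure(rep(TRUE, length(x)), degenerate = TRUE))
  x >= med - k * mad & x <= med + k * mad
}

mask_transform <- function(x, z_crit = 2) {
  if (length(x) < 3L) return(rep(TRUE, length(x)))
  rng <- max(x) - min(x)
  if (rng == 0)
    return(structure(rep(TRUE, length(x)), degenerate = TRUE))
  y <- sqrt((x - min(x)) / rng)
  s <- stats::sd(y)
  if (s == 0)
    return(structure(rep(TRUE, length(x)), degenerate = TRUE))
  z <- (y - mean(y)) / s
  abs(z) <= z_crit
}

mask_for_method <- function(method, x) {
  switch(method,
         "no" = mask_none(x),
         "cutoff" = mask_cutoff(x),
         "2sd" = mask_sd(x, 2),
         "3sd" = mask_sd(x, 3),
         "tukey1.5" = mask_tukey(x, 1.5),
         "q10" = mask_quantile(x, 0.05),
         "q05" = mask_quantile(x, 0.025),
         "MAD" = mask_mad(x, 1.4826),
         "MAD_adjusted" = mask_mad(x, 1.1020),
         "transform" = mask_transform(x, 2),
         stop(sprintf("unknown exclusion method '%s'", method)))
}

# ---- public outcome API -------------------------------------------------

new_exclusion_outcome <- function(x, kept, lower = NA_real_, upper = NA_real_) {
  n <- length(x)
  excl <- !kept
  if (any(kept)) {
    # every rule keeps an interval, so excluded values sit below or
    # above the kept range; classify tails against that range rather
    # than the thresholds to stay exact under floating point
    n_low <- sum(excl & x < min(x[kept]))
    n_high <- sum(excl & x > max(x[kept]))
  } else {
    n_low <- if (!is.na(lower)) sum(excl & x < lower) else 0L
    n_high <- sum(excl) - n_low
  }
  structure(list(
    kept_mask = kept,
    lower_threshold = lower,
    upper_threshold = upper,
    prop_excluded_low = n_low / n,
    prop_excluded_high = n_high / n
  ), class = "exclusion_outcome")
}

#' @export
print.exclusion_outcome <- function(x, ...) {
  n <- length(x$kept_mask)
  cat(sprintf("Exclusion outcome: kept %d of %d (%.1f%% low tail, %.1f%% high tail excluded)\n",
              sum(x$kept_mask), n,
              100 * x$prop_excluded_low, 100 * x$prop_excluded_high))
  if (!is.na(x$lower_threshold) || !is.na(x$upper_threshold))
    cat(sprintf("  thresholds: [%.2f, %.2f] ms\n",
                x$lower_threshold, x$upper_threshold))
  invisible(x)
}

#' Keep all RTs (no outlier exclusion)
#'
#' @param rts Numeric RT vector (ms).
#' @return An `exclusion_outcome`: list with `kept_mask`,
#'   `lower_threshold`, `upper_threshold`, `prop_excluded_low`,
#'   `prop_excluded_high`.
#' @export
exclude_none <- function(rts) {
  stopifnot(is.numeric(rts), length(rts) >= 1L)
  new_exclusion_outcome(rts, mask_none(rts))
}

#' Exclude RTs outside a-priori cutoffs
#'
#' Excludes RTs below 200 ms (below plausible stimulus encoding and
#' response execution time) or above the sample mean + 1000 ms. The mean
#' is computed on the input vector.
#'
#' @inheritParams exclude_none
#' @return An `exclusion_outcome` (see [exclude_none()]).
#' @examples
#' exclude_cutoff(c(150, 300, 400, 2000))  # drops 150 and 2000
#' @export
exclude_cutoff <- function(rts) {
  stopifnot(is.numeric(rts), length(rts) >= 1L)
  new_exclusion_outcome(rts, mask_cutoff(rts), 200, mean(rts) + 1000)
}

#' Exclude RTs outside mean +/- k standard deviations
#'
#' @inheritParams exclude_none
#' @param k SD multiple, conventionally 2 or 3.
#' @return An `exclusion_outcome` (see [exclude_none()]).
#' @export
exclude_sd <- function(rts, k = 2) {
  stopifnot(is.numeric(rts), length(rts) >= 1L, k > 0)
  if (length(rts) < 2L) {
    warning("fewer than 2 values; SD undefined, nothing excluded")
    return(new_exclusion_outcome(rts, mask_none(rts)))
  }
  m <- mean(rts)
  s <- stats::sd(rts)
  new_exclusion_outcome(rts, mask_sd(rts, k), m - k * s, m + k * s)
}

#' Exclude RTs outside the Tukey fences
#'
#' The boxplot criterion: values beyond `q0.25 - c * IQR` or
#' `q0.75 + c * IQR` are excluded. Quartiles use linear interpolation of
#' order statistics (R's default type-7 convention).
#'
#' @inheritParams exclude_none
#' @param c Fence multiplier (default 1.5).
#' @return An `exclusion_outcome` (see [exclude_none()]).
#' @export
exclude_tukey <- function(rts, c = 1.5) {
  stopifnot(is.numeric(rts), length(rts) >= 1L, c > 0)
  if (length(rts) < 4L) {
    warning("fewer than 4 values; quartiles unstable, nothing excluded")
    return(new_exclusion_outcome(rts, mask_none(rts)))
  }
  q <- stats::quantile(rts, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2L] - q[1L]
  new_exclusion_outcome(rts, mask_tukey(rts, c), q[1L] - c * iqr, q[2L] + c * iqr)
}

#' Exclude RTs outside symmetric sample quantiles
#'
#' Excludes values strictly below the `p` quantile or strictly above the
#' `1 - p` quantile (type-7 interpolated quantiles), aiming at a fixed
#' excluded share of about `2 p`. In small samples the realised share
#' deviates from `2 p` because a fractional number of RTs cannot be
#' excluded.
#'
#' @inheritParams exclude_none
#' @param p Tail mass per side: 0.05 for the outer 10%, 0.025 for the
#'   outer 5%.
#' @return An `exclusion_outcome` (see [exclude_none()]).
#' @export
exclude_quantile <- function(rts, p = 0.05) {
  stopifnot(is.numeric(rts), length(rts) >= 2L, p > 0, p < 0.5)
  q <- stats::quantile(rts, c(p, 1 - p), names = FALSE, type = 7)
  new_exclusion_outcome(rts, mask_quantile(rts, p), q[1L], q[2L])
}

#' Exclude RTs outside median +/- 2.5 MAD
#'
#' MAD = b * median(|x - median(x)|). With b = 1.4826 the MAD estimates
#' the SD of normal data; b = 1.1020 is the adjustment calibrated to the
#' Ex-Gaussian shape of RT distributions, which yields a smaller MAD and
#' therefore a stricter criterion.
#'
#' @inheritParams exclude_none
#' @param b MAD scale constant, 1.4826 or 1.1020.
#' @param k Multiple of the MAD beyond the median (default 2.5).
#' @return An `exclusion_outcome` (see [exclude_none()]).
#' @export
exclude_mad <- function(rts, b = 1.4826, k = 2.5) {
  stopifnot(is.numeric(rts), length(rts) >= 1L, b > 0, k > 0)
  if (length(rts) < 2L) {
    warning("fewer than 2 values; nothing excluded")
    return(new_exclusion_outcome(rts, mask_none(rts)))
  }
  med <- stats::median(rts)
  mad <- b * stats::median(abs(rts - med))
  if (mad == 0) {
    warning("MAD is zero (over half the values identical); nothing excluded")
    return(new_exclusion_outcome(rts, mask_none(rts)))
  }
  new_exclusion_outcome(rts, mask_mad(rts, b, k), med - k * mad, med + k * mad)
}

#' Exclude RTs by z-scoring square-root range-normalised values
#'
#' Transforms each RT to `y = sqrt((x - min(x)) / (max(x) - min(x)))`,
#' which bounds values in [0, 1] and symmetrises the right-skewed RT
#' shape, then z-scores y (sample SD) and excludes values with
#' |z| > `z_crit`.
#'
#' @inheritParams exclude_none
#' @param z_crit z-score criterion (default 2).
#' @return An `exclusion_outcome` (see [exclude_none()]). The reported
#'   thresholds are on the RT scale (the transform is monotone).
#' @export
exclude_transform <- function(rts, z_crit = 2) {
  stopifnot(is.numeric(rts), length(rts) >= 1L, z_crit > 0)
  if (length(rts) < 3L) {
    warning("fewer than 3 values; nothing excluded")
    return(new_exclusion_outcome(rts, mask_none(rts)))
  }
  rng <- max(rts) - min(rts)
  if (rng == 0) {
    warning("degenerate range (all values equal); nothing excluded")
    return(new_exclusion_outcome(rts, mask_none(rts)))
  }
  y <- sqrt((rts - min(rts)) / rng)
  s <- stats::sd(y)
  kept <- mask_transform(rts, z_crit)
  # back-transform the z bounds to the RT scale for reporting
  y_lo <- mean(y) - z_crit * s
  y_hi <- mean(y) + z_crit * s
  lo <- if (y_lo > 0) min(rts) + y_lo^2 * rng else NA_real_
  hi <- if (y_hi < 1) min(rts) + y_hi^2 * rng else NA_real_
  new_exclusion_outcome(rts, kept, lo, hi)
}

#' Apply a named exclusion method
#'
#' Dispatches over the method registry of [exclusion_methods()] and
#' returns the rule's outcome, with excluded proportions reported
#' relative to the input length.
#'
#' @param method One of the ten method names (see
#'   [exclusion_methods()]).
#' @param rts Numeric RT vector (ms).
#' @return An `exclusion_outcome` (see [exclude_none()]).
#' @examples
#' apply_method("2sd", c(300, 320, 340, 360, 380, 400, 2000))
#' @export
apply_method <- function(method, rts) {
  stopifnot(is.character(method), length(method) == 1L)
  if (!method %in% .method_names)
    stop(sprintf("unknown exclusion method '%s'; see exclusion_methods()", method))
  switch(method,
         "no" = exclude_none(rts),
         "cutoff" = exclude_cutoff(rts),
         "2sd" = exclude_sd(rts, 2),
         "3sd" = exclude_sd(rts, 3),
         "tukey1.5" = exclude_tukey(rts, 1.5),
         "q10" = exclude_quantile(rts, 0.05),
         "q05" = exclude_quantile(rts, 0.025),
         "MAD" = exclude_mad(rts, 1.4826),
         "MAD_adjusted" = exclude_mad(rts, 1.1020),
         "transform" = exclude_transform(rts, 2))
}
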