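#' Draw an outlier plan for one sample pair
#'
#' Determines how many valid RTs are replaced by outliers and how the
#' outliers split into long (slow) and short (fast) ones. The outlier
#' count is round(u) with u ~ U(0, 0.1 N), so samples carry between 0%
#' and 10% outliers; the long-outlier share is a Beta(5, 1) draw
#' (expected value 5/6, reflecting the physiologically narrower range
#' available to fast outliers). One plan is drawn per pair and shared by
#' both conditions, so the outlier counts are fixed across conditions
#' while the outlier values are drawn independently per condition.
#'
#' Counts are rounded with round-half-to-even; the short count is the
#' remainder `n_outliers - n_long` so the split always sums correctly.
#'
#' @param n_trials Trials per condition (>= 20).
#' @return An object of class `outlier_plan`: list with `n_outliers`,
#'   `n_long`, `n_short`, `p_long`.
#' @examples
#' set.seed(1)
#' draw_outlier_plan(60)
#' @export
draw_outlier_plan <- function(n_trials) {
  stopifnot(is.numeric(n_trials), length(n_trials) == 1L, n_trials >= 20)
  n_out <- as.integer(round(stats::runif(1, 0, 0.1 * n_trials)))
  p_long <- stats::rbeta(1, 5, 1)
  n_long <- as.integer(round(p_long * n_out))
  structure(list(
    n_outliers = n_out,
    n_long = n_long,
    n_short = n_out - n_long,
    p_long = p_long
  ), class = "outlier_plan")
}

#' @export
print.outlier_plan <- function(x, ...) {
  cat(sprintf("Outlier plan: %d outliers (%d long, %d short; P(long) = %.3f)\n",
              x$n_outliers, x$n_long, x$n_short, x$p_long))
  invisible(x)
}

new_contaminated_sample <- function(values, flag, tail, valid) {
  structure(list(values = values, outlier_flag = flag,
                 tail_label = tail, valid_reference = valid),
            class = "contaminated_sample")
}

#' @export
print.contaminated_sample <- function(x, ...) {
  cat(sprintf("Contaminated RT sample: n = %d, %d outliers (%d long, %d short)\n",
              length(x$values), sum(x$outlier_flag),
              sum(x$tail_label == "long"), sum(x$tail_label == "short")))
  invisible(x)
}

# Pick positions and splice outlier values into the valid vector.
replace_positions <- function(valid, long_vals, short_vals) {
  n <- length(valid)
  n_long <- length(long_vals)
  n_short <- length(short_vals)
  k <- n_long + n_short
  flag <- logical(n)
  tail <- rep("none", n)
  values <- valid
  if (k > 0L) {
    pos <- sample.int(n, k)   # uniform without replacement
    long_pos <- pos[seq_len(n_long)]
    short_pos <- pos[seq_len(n_short) + n_long]
    values[long_pos] <- long_vals
    values[short_pos] <- short_vals
    flag[pos] <- TRUE
    tail[long_pos] <- "long"
    tail[short_pos] <- "short"
  }
  new_contaminated_sample(values, flag, tail, valid)
}

#' Inject outliers strictly outside the valid range ("tails" approach)
#'
#' Long outliers are uniform on (max(valid), max(valid) + 2000 ms), so
#' every long outlier exceeds the pre-contamination maximum. Short
#' outliers are `U(0,1) * (min(valid) - 100) + 100`, i.e. uniform on
#' (100, min(valid)) whenever the valid minimum exceeds 100 ms, so every
#' short outlier undercuts the pre-contamination minimum. If the valid
#' minimum is at or below 100 ms (possible but rare under the
#' generator), short outliers are drawn uniform on (0, min(valid)) and a
#' warning is emitted. Replaced positions are chosen uniformly without
#' replacement; the sample size is unchanged.
#'
#' @param valid Numeric vector of valid RTs (ms).
#' @param plan An [draw_outlier_plan()] result consistent with
#'   `length(valid)`.
#' @return A `contaminated_sample`: list with `values`, `outlier_flag`,
#'   `tail_label` (`"long"`, `"short"` or `"none"` per element) and
#'   `valid_reference`.
#' @export
inject_tails <- function(valid, plan) {
  stopifnot(is.numeric(valid), inherits(plan, "outlier_plan"),
            plan$n_outliers <= length(valid))
  long_vals <- stats::runif(plan$n_long) * 2000 + max(valid)
  lo <- min(valid)
  if (plan$n_short > 0L && lo <= 100) {
    warning("valid minimum at or below 100 ms; short outliers drawn on (0, min)")
    short_vals <- stats::runif(plan$n_short) * lo
  } else {
    short_vals <- stats::runif(plan$n_short) * (lo - 100) + 100
  }
  replace_positions(valid, long_vals, short_vals)
}

#' Inject outliers overlapping the valid distribution ("overlap" approach)
#'
#' Outliers are drawn from Ex-Gaussian distributions positioned relative
#' to the valid sample mean, so they can fall inside the valid range.
#' Long outliers: ExGaussian(mu = mean(valid) + 700, sigma = U(20, 50) + 10,
#' tau = U(150, 200)); sigma and tau are drawn once per call (one
#' contaminant distribution per sample). Short outliers:
#' ExGaussian(mu = mean(valid) - 200, sigma = 20, tau = 10); any negative
#' generated value is multiplied by -1 so RTs stay positive.
#'
#' @inheritParams inject_tails
#' @return A `contaminated_sample` (see [inject_tails()]).
#' @export
inject_overlap <- function(valid, plan) {
  stopifnot(is.numeric(valid), inherits(plan, "outlier_plan"),
            plan$n_outliers <= length(valid))
  m <- mean(valid)
  long_vals <- numeric(0)
  if (plan$n_long > 0L) {
    p_long <- exg_params(m + 700, stats::runif(1, 20, 50) + 10,
                         stats::runif(1, 150, 200))
    long_vals <- sample_exgauss(p_long, plan$n_long)
  }
  short_vals <- numeric(0)
  if (plan$n_short > 0L) {
    mu_short <- m - 200
    # mu may be any real here; only the realised RT is reflected to stay positive
    short_vals <- stats::rnorm(plan$n_short, mu_short, 20) +
      stats::rexp(plan$n_short, rate = 1 / 10)
    short_vals <- abs(short_vals)
  }
  long_vals <- abs(long_vals)
  replace_positions(valid, long_vals, short_vals)
}

#' Contaminate both conditions of a sample pair
#'
#' Applies the same outlier plan (fixed counts) to both conditions;
#' outlier values and replaced positions are drawn independently per
#' condition.
#'
#' @param pair A list with `cond1` and `cond2` RT vectors of equal
#'   length (see [make_pair()]).
#' @param plan An [draw_outlier_plan()] result.
#' @param approach `"tails"` or `"overlap"`.
#' @return List with two `contaminated_sample` objects, `cond1` and
#'   `cond2`.
#' @examples
#' set.seed(1)
#' cfg <- draw_pair_config()
#' pair <- make_pair(cfg, diff = 0)
#' contaminate_pair(pair, draw_outlier_plan(cfg$n_trials), "tails")
#' @export
contaminate_pair <- function(pair, plan, approach = c("tails", "overlap")) {
  approach <- match.arg(approach)
  if (length(pair$cond1) != length(pair$cond2))
    stop("conditions must have the same number of trials")
  inject <- if (approach == "tails") inject_tails else inject_overlap
  list(cond1 = inject(pair$cond1, plan),
       cond2 = inject(pair$cond2, plan))
}
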