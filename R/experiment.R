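#' Simulation configuration
#'
#' Assembles and validates the settings of a simulation run. The
#' defaults are the full study design: population mean differences 0
#' to 100 ms in 1 ms steps, 5000 sample pairs per difference, both
#' contamination approaches, and all ten exclusion methods.
#'
#' @param diffs Numeric vector of population mean differences (ms).
#' @param reps Sample pairs simulated per difference level (>= 1).
#' @param approaches Subset of `c("tails", "overlap")`.
#' @param methods Subset of the ten method names
#'   ([exclusion_methods()]).
#' @param seed Master seed; every random draw of the run flows from it.
#' @param alpha Significance level for the t-tests (default 0.05).
#' @param min_n Minimum per-condition observations required after
#'   exclusion for the t-test; below it the iteration is recorded as
#'   non-significant for that method (default 3).
#' @param output_dir Optional directory for [write_experiment()].
#' @return An object of class `sim_config`.
#' @examples
#' sim_config(diffs = c(0, 50, 100), reps = 10, seed = 1)
#' @export
sim_config <- function(diffs = 0:100,
                       reps = 5000,
                       approaches = c("tails", "overlap"),
                       methods = exclusion_methods()$method,
                       seed = 1L,
                       alpha = 0.05,
                       min_n = 3L,
                       output_dir = NULL) {
  stopifnot(is.numeric(diffs), length(diffs) >= 1L, all(diffs >= 0),
            is.numeric(reps), length(reps) == 1L, reps >= 1,
            is.numeric(seed), length(seed) == 1L,
            is.numeric(alpha), alpha > 0, alpha < 1,
            is.numeric(min_n), min_n >= 2)
  approaches <- match.arg(approaches, c("tails", "overlap"), several.ok = TRUE)
  if (length(methods) < 1L) stop("'methods' must name at least one exclusion method")
  bad <- setdiff(methods, .method_names)
  if (length(bad))
    stop(sprintf("unknown exclusion method(s): %s", paste(bad, collapse = ", ")))
  structure(list(diffs = as.numeric(diffs), reps = as.integer(reps),
                 approaches = approaches, methods = as.character(methods),
                 seed = as.integer(seed), alpha = alpha,
                 min_n = as.integer(min_n), output_dir = output_dir),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  %d difference levels (%g..%g ms), %d pairs each\n",
              length(x$diffs), min(x$diffs), max(x$diffs), x$reps))
  cat(sprintf("  approaches: %s\n", paste(x$approaches, collapse = ", ")))
  cat(sprintf("  methods: %s\n", paste(x$methods, collapse = ", ")))
  cat(sprintf("  seed %d, alpha %g, min n after exclusion %d\n",
              x$seed, x$alpha, x$min_n))
  invisible(x)
}

# classify an exclusion mask's removed values into low/high tail counts
tail_counts <- function(x, kept) {
  if (all(kept)) return(c(0L, 0L))
  if (!any(kept)) return(c(sum(x < 200), sum(x >= 200)))  # only 'cutoff' can do this
  xk <- x[kept]
  c(sum(!kept & x < min(xk)), sum(!kept & x > max(xk)))
}

#' Run the full simulation experiment
#'
#' For every approach x difference x iteration: draws a pair
#' configuration, simulates the valid RT pair, contaminates it,
#' applies every exclusion method, runs the pooled t-test on the valid
#' pair and on each post-exclusion pair, and records the results. The
#' records are then aggregated into the bias summary, descriptive
#' statistics, the t-value regression and the |bias| vs
#' excluded-proportion correlations.
#'
#' Every iteration runs under its own seed derived from the master
#' seed, so reruns are identical and any single iteration can be
#' reproduced in isolation.
#'
#' @param config A [sim_config()].
#' @param progress Print one status line per approach (default FALSE).
#' @return An object of class `rt_experiment`: list with
#' \describe{
#'   \item{records}{data.frame, one row per iteration x approach x
#'     method plus one `"valid"` pseudo-method row per iteration: t, p,
#'     significance, post-exclusion n and SD per condition, and the
#'     low/high-tail excluded proportions (averaged over conditions).}
#'   \item{samples}{data.frame of per-sample descriptives (mean, SD,
#'     skewness, n) for valid and contaminated samples.}
#'   \item{bias}{[compute_bias()] result.}
#'   \item{descriptives}{[descriptive_stats()] result.}
#'   \item{regression}{[regress_t_values()] result (NULL if fewer than
#'     two methods were run).}
#'   \item{correlations}{[bias_exclusion_correlation()] result (NULL
#'     where undefined).}
#'   \item{counters}{named counts of degenerate events: tests skipped
#'     for small post-exclusion n (per method), degenerate exclusion
#'     statistics (MAD = 0 or zero range, per method), undefined tests,
#'     and short-outlier draws with a valid minimum at or below
#'     100 ms.}
#'   \item{config}{the configuration used.}
#' }
#' @examples
#' res <- run_experiment(sim_config(diffs = c(0, 100), reps = 20, seed = 42))
#' res$bias$table
#' @export
run_experiment <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  methods <- config$methods
  M <- length(methods)
  diffs <- config$diffs
  reps <- config$reps
  alpha <- config$alpha
  min_n <- config$min_n

  n_iter <- length(config$approaches) * length(diffs) * reps
  per_iter <- 1L + M
  n_rows <- n_iter * per_iter

  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_iter)

  # result columns filled in the loop
  t_v <- numeric(n_rows); p_v <- numeric(n_rows); sig_v <- logical(n_rows)
  n1_v <- integer(n_rows); n2_v <- integer(n_rows)
  sd1_v <- numeric(n_rows); sd2_v <- numeric(n_rows)
  plo_v <- numeric(n_rows); phi_v <- numeric(n_rows)

  s_n <- integer(2L * n_iter)
  s_vmean <- numeric(2L * n_iter); s_vsd <- numeric(2L * n_iter)
  s_vskew <- numeric(2L * n_iter)
  s_cmean <- numeric(2L * n_iter); s_csd <- numeric(2L * n_iter)
  s_cskew <- numeric(2L * n_iter)

  small_n <- stats::setNames(integer(M), methods)
  degenerate_stat <- stats::setNames(integer(M), methods)
  n_undefined <- 0L
  n_short_low_min <- 0L

  it <- 0L
  for (approach in config$approaches) {
    if (progress)
      message(sprintf("approach '%s': %d diffs x %d reps", approach,
                      length(diffs), reps))
    tails <- approach == "tails"
    for (d in diffs) {
      for (rep_i in seq_len(reps)) {
        it <- it + 1L
        set.seed(seeds[it])
        cfg <- draw_pair_config()
        pair <- make_pair(cfg, d)
        plan <- draw_outlier_plan(cfg$n_trials)
        cont <- withCallingHandlers(
          contaminate_pair(pair, plan, approach),
          warning = function(w) {
            n_short_low_min <<- n_short_low_min + 1L
            invokeRestart("muffleWarning")
          })
        x1 <- cont$cond1$values
        x2 <- cont$cond2$values
        N <- cfg$n_trials

        r <- (it - 1L) * per_iter + 1L
        # "valid" pseudo-method row: the uncontaminated pair
        tp <- pooled_t_stat(pair$cond2, pair$cond1)
        t_v[r] <- tp[1L]; p_v[r] <- tp[2L]
        sig_v[r] <- is.finite(tp[2L]) && tp[2L] < alpha
        n1_v[r] <- N; n2_v[r] <- N
        sd1_v[r] <- stats::sd(pair$cond1); sd2_v[r] <- stats::sd(pair$cond2)

        si <- (it - 1L) * 2L
        s_n[si + 1L] <- N; s_n[si + 2L] <- N
        s_vmean[si + 1L] <- mean(pair$cond1); s_vmean[si + 2L] <- mean(pair$cond2)
        s_vsd[si + 1L] <- sd1_v[r]; s_vsd[si + 2L] <- sd2_v[r]
        s_vskew[si + 1L] <- sample_skewness(pair$cond1)
        s_vskew[si + 2L] <- sample_skewness(pair$cond2)
        s_cmean[si + 1L] <- mean(x1); s_cmean[si + 2L] <- mean(x2)
        s_csd[si + 1L] <- stats::sd(x1); s_csd[si + 2L] <- stats::sd(x2)
        s_cskew[si + 1L] <- sample_skewness(x1)
        s_cskew[si + 2L] <- sample_skewness(x2)

        for (mi in seq_len(M)) {
          m <- methods[mi]
          k1 <- mask_for_method(m, x1)
          k2 <- mask_for_method(m, x2)
          if (!is.null(attr(k1, "degenerate")) || !is.null(attr(k2, "degenerate")))
            degenerate_stat[mi] <- degenerate_stat[mi] + 1L
          k1 <- as.vector(k1)
          k2 <- as.vector(k2)
          x1k <- x1[k1]; x2k <- x2[k2]
          n1 <- length(x1k); n2 <- length(x2k)
          rr <- r + mi
          n1_v[rr] <- n1; n2_v[rr] <- n2
          sd1_v[rr] <- if (n1 > 1L) stats::sd(x1k) else NA_real_
          sd2_v[rr] <- if (n2 > 1L) stats::sd(x2k) else NA_real_
          tc1 <- tail_counts(x1, k1); tc2 <- tail_counts(x2, k2)
          plo_v[rr] <- (tc1[1L] / N + tc2[1L] / N) / 2
          phi_v[rr] <- (tc1[2L] / N + tc2[2L] / N) / 2
          if (n1 < min_n || n2 < min_n) {
            small_n[mi] <- small_n[mi] + 1L
            t_v[rr] <- NA_real_; p_v[rr] <- NA_real_; sig_v[rr] <- FALSE
          } else {
            tp <- pooled_t_stat(x2k, x1k)
            if (!is.finite(tp[2L])) n_undefined <- n_undefined + 1L
            t_v[rr] <- tp[1L]; p_v[rr] <- tp[2L]
            sig_v[rr] <- is.finite(tp[2L]) && tp[2L] < alpha
          }
        }
      }
    }
  }

  block <- length(diffs) * reps * per_iter
  records <- data.frame(
    iteration = rep(seq_len(n_iter), each = per_iter),
    approach = rep(config$approaches, each = block),
    diff = rep(rep(diffs, each = reps * per_iter), times = length(config$approaches)),
    method = rep(c("valid", methods), times = n_iter),
    t = t_v, p = p_v, significant = sig_v,
    n1 = n1_v, n2 = n2_v, sd1 = sd1_v, sd2 = sd2_v,
    prop_excl_low = plo_v, prop_excl_high = phi_v,
    stringsAsFactors = FALSE
  )
  sblock <- length(diffs) * reps * 2L
  samples <- data.frame(
    iteration = rep(seq_len(n_iter), each = 2L),
    approach = rep(config$approaches, each = sblock),
    diff = rep(rep(diffs, each = reps * 2L), times = length(config$approaches)),
    condition = rep(1:2, times = n_iter),
    n = s_n, valid_mean = s_vmean, valid_sd = s_vsd, valid_skew = s_vskew,
    cont_mean = s_cmean, cont_sd = s_csd, cont_skew = s_cskew,
    stringsAsFactors = FALSE
  )

  bias <- compute_bias(records)
  descriptives <- descriptive_stats(samples)
  # not estimable for every config (single method, constant diff, ...)
  regression <- tryCatch(regress_t_values(records), error = function(e) NULL)
  correlations <- tryCatch(bias_exclusion_correlation(bias, records),
                           error = function(e) NULL)

  structure(list(records = records, samples = samples, bias = bias,
                 descriptives = descriptives, regression = regression,
                 correlations = correlations,
                 counters = list(small_n_skipped = small_n,
                                 degenerate_statistic = degenerate_stat,
                                 undefined_tests = n_undefined,
                                 short_outlier_low_min = n_short_low_min),
                 config = config),
            class = "rt_experiment")
}

#' @export
print.rt_experiment <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("RT outlier-exclusion experiment: %d iterations (%d diffs x %d reps x %d approach%s)\n",
              length(cfg$approaches) * length(cfg$diffs) * cfg$reps,
              length(cfg$diffs), cfg$reps, length(cfg$approaches),
              if (length(cfg$approaches) > 1L) "es" else ""))
  cat("\nMean bias per method (cross-approach):\n")
  print(x$bias$table, row.names = FALSE, digits = 3)
  invisible(x)
}
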