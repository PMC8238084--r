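#' Ex-Gaussian parameter triple
#'
#' Bundles the three parameters of an Ex-Gaussian response-time
#' distribution: the convolution of a Normal(mu, sigma) and an
#' Exponential with mean tau. Its mean is mu + tau, its variance
#' sigma^2 + tau^2, and its skewness 2 tau^3 / (sigma^2 + tau^2)^(3/2).
#' All three parameters are in milliseconds.
#'
#' @param mu Mean of the Gaussian component (ms), > 0.
#' @param sigma Standard deviation of the Gaussian component (ms), > 0.
#' @param tau Mean of the exponential component (ms), > 0.
#' @return An object of class `exg_params`.
#' @examples
#' exg_params(400, 30, 175)
#' @export
exg_params <- function(mu, sigma, tau) {
  stopifnot(is.numeric(mu), is.numeric(sigma), is.numeric(tau),
            length(mu) == 1L, length(sigma) == 1L, length(tau) == 1L)
  if (!is.finite(mu) || mu <= 0) stop("'mu' must be a positive number")
  if (!is.finite(sigma) || sigma <= 0) stop("'sigma' must be a positive number")
  if (!is.finite(tau) || tau <= 0) stop("'tau' must be a positive number")
  structure(list(mu = mu, sigma = sigma, tau = tau), class = "exg_params")
}

#' @export
print.exg_params <- function(x, ...) {
  cat(sprintf("Ex-Gaussian parameters: mu = %.1f ms, sigma = %.1f ms, tau = %.1f ms\n",
              x$mu, x$sigma, x$tau))
  cat(sprintf("  population mean %.1f ms, SD %.1f ms\n",
              x$mu + x$tau, sqrt(x$sigma^2 + x$tau^2)))
  invisible(x)
}

#' Draw the population configuration for one sample pair
#'
#' Draws the shared trial number and base Ex-Gaussian parameters for a
#' pair of simulated RT conditions. The trial number N is an integer
#' uniform on 20..100; mu ~ U(250, 500), sigma ~ U(20, 50) and
#' tau ~ U(150, 200) are continuous. N, sigma and tau are held constant
#' within a pair; the population mean difference between the two
#' conditions (`diff`) is not part of the configuration and is supplied
#' by the experiment grid.
#'
#' Uses the current R random-number stream (`set.seed()` for
#' reproducibility).
#'
#' @return An object of class `pair_config`: a list with `n_trials` and
#'   `base_params` (an [exg_params()]).
#' @examples
#' set.seed(1)
#' draw_pair_config()
#' @export
draw_pair_config <- function() {
  structure(list(
    n_trials = sample.int(81L, 1L) + 19L,   # integer uniform on {20, ..., 100}
    base_params = exg_params(
      mu = stats::runif(1, 250, 500),
      sigma = stats::runif(1, 20, 50),
      tau = stats::runif(1, 150, 200)
    )
  ), class = "pair_config")
}

#' @export
print.pair_config <- function(x, ...) {
  cat(sprintf("RT pair configuration: N = %d trials per condition\n", x$n_trials))
  print(x$base_params)
  invisible(x)
}

#' Sample from an Ex-Gaussian distribution
#'
#' Each value is a Normal(mu, sigma) draw plus an independent
#' Exponential draw with mean tau.
#'
#' @param params An [exg_params()] object.
#' @param n Number of values to draw.
#' @return Numeric vector of length `n` (ms).
#' @examples
#' set.seed(1)
#' mean(sample_exgauss(exg_params(400, 30, 175), 1e4))  # close to 575
#' @export
sample_exgauss <- function(params, n) {
  if (!inherits(params, "exg_params")) params <- do.call(exg_params, as.list(params))
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  stats::rnorm(n, params$mu, params$sigma) + stats::rexp(n, rate = 1 / params$tau)
}

#' Simulate one pair of valid RT samples
#'
#' Condition 1 is sampled from the configuration's base parameters;
#' condition 2 from the same parameters with `diff` ms added to mu.
#' Both samples have `n_trials` values; N, sigma and tau are shared.
#'
#' @param config A [draw_pair_config()] result.
#' @param diff Population mean difference in ms, >= 0.
#' @return A list with numeric vectors `cond1` and `cond2`.
#' @examples
#' set.seed(1)
#' pair <- make_pair(draw_pair_config(), diff = 50)
#' mean(pair$cond2) - mean(pair$cond1)
#' @export
make_pair <- function(config, diff) {
  stopifnot(inherits(config, "pair_config"),
            is.numeric(diff), length(diff) == 1L, diff >= 0)
  p <- config$base_params
  shifted <- exg_params(p$mu + diff, p$sigma, p$tau)
  list(cond1 = sample_exgauss(p, config$n_trials),
       cond2 = sample_exgauss(shifted, config$n_trials))
}

# Moment-ratio sample skewness g1 = m3 / m2^(3/2) with central moments
# computed with the 1/n denominator.
sample_skewness <- function(x) {
  n <- length(x)
  if (n < 3L) return(NA_real_)
  d <- x - mean(x)
  m2 <- sum(d^2) / n
  if (m2 == 0) return(NA_real_)
  (sum(d^3) / n) / m2^1.5
}
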