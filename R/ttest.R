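#' Pooled-variance two-sample t-test
#'
#' Student's independent two-sample t-test with pooled variance
#' (variance equality is assumed by design: both simulated conditions
#' share sigma and tau). The statistic is oriented as
#' `mean(a) - mean(b)`; the p-value is two-sided from the t distribution
#' with `n1 + n2 - 2` degrees of freedom. Unequal sample sizes, as they
#' arise after outlier exclusion, are handled by the pooled formula.
#'
#' If either side has fewer than 2 observations the test is undefined;
#' the result carries `t = NA`, `p = NA`, is flagged non-significant,
#' and a warning is emitted.
#'
#' @param a,b Numeric RT vectors.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `rt_test`: list with `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, `significant`.
#' @examples
#' pooled_t_test(c(1, 2, 3), c(2, 3, 4))
#' @export
pooled_t_test <- function(a, b, alpha = 0.05) {
  stopifnot(is.numeric(a), is.numeric(b), alpha > 0, alpha < 1)
  n1 <- length(a)
  n2 <- length(b)
  if (n1 < 2L || n2 < 2L) {
    warning("fewer than 2 observations on one side; test undefined")
    return(structure(list(t_statistic = NA_real_,
                          degrees_of_freedom = n1 + n2 - 2L,
                          p_value = NA_real_, significant = FALSE),
                     class = "rt_test"))
  }
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / df
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(t), df)
  structure(list(t_statistic = t, degrees_of_freedom = df,
                 p_value = p, significant = is.finite(p) && p < alpha),
            class = "rt_test")
}

#' @export
print.rt_test <- function(x, ...) {
  cat(sprintf("Pooled two-sample t-test: t(%d) = %.4f, p = %.4g%s\n",
              x$degrees_of_freedom, x$t_statistic, x$p_value,
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

# Hot-path scalar version used by the simulation loop: returns
# c(t, p) without object construction; NA when undefined.
pooled_t_stat <- function(a, b) {
  n1 <- length(a)
  n2 <- length(b)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / df
  if (!is.finite(sp2) || sp2 <= 0) return(c(NA_real_, NA_real_))
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  c(t, 2 * stats::pt(-abs(t), df))
}
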