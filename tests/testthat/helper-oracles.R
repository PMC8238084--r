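# Brute-force reimplementation of the exclusion rules, written
# element-wise from the rule definitions and kept independent of the
# package implementation (own quantile interpolation, own SD/median).

oracle_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  j <- floor(h)
  g <- h - j
  if (j >= n) s[n] else s[j] + g * (s[j + 1] - s[j])
}

oracle_sd <- function(x) sqrt(sum((x - sum(x) / length(x))^2) / (length(x) - 1))

oracle_median <- function(x) oracle_quantile(x, 0.5)

# keep mask per the rule inequalities, evaluated one element at a time
oracle_mask <- function(method, x) {
  n <- length(x)
  inside <- function(lo, hi) {
    keep <- logical(n)
    for (i in seq_len(n)) keep[i] <- !(x[i] < lo || x[i] > hi)
    keep
  }
  switch(method,
    "no" = rep(TRUE, n),
    "cutoff" = inside(200, sum(x) / n + 1000),
    "2sd" = {
      m <- sum(x) / n; s <- oracle_sd(x)
      if (!is.finite(s)) rep(TRUE, n) else inside(m - 2 * s, m + 2 * s)
    },
    "3sd" = {
      m <- sum(x) / n; s <- oracle_sd(x)
      if (!is.finite(s)) rep(TRUE, n) else inside(m - 3 * s, m + 3 * s)
    },
    "tukey1.5" = {
      q1 <- oracle_quantile(x, 0.25); q3 <- oracle_quantile(x, 0.75)
      inside(q1 - 1.5 * (q3 - q1), q3 + 1.5 * (q3 - q1))
    },
    "q10" = inside(oracle_quantile(x, 0.05), oracle_quantile(x, 0.95)),
    "q05" = inside(oracle_quantile(x, 0.025), oracle_quantile(x, 0.975)),
    "MAD" = {
      med <- oracle_median(x)
      mad <- 1.4826 * oracle_median(abs(x - med))
      if (mad == 0) rep(TRUE, n) else inside(med - 2.5 * mad, med + 2.5 * mad)
    },
    "MAD_adjusted" = {
      med <- oracle_median(x)
      mad <- 1.1020 * oracle_median(abs(x - med))
      if (mad == 0) rep(TRUE, n) else inside(med - 2.5 * mad, med + 2.5 * mad)
    },
    "transform" = {
      rng <- max(x) - min(x)
      if (rng == 0) return(rep(TRUE, n))
      y <- sqrt((x - min(x)) / rng)
      s <- oracle_sd(y)
      if (s == 0) return(rep(TRUE, n))
      keep <- logical(n)
      for (i in seq_len(n)) keep[i] <- abs((y[i] - sum(y) / n) / s) <= 2
      keep
    },
    stop("unknown method"))
}

all_method_names <- function() exclusion_methods()$method
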