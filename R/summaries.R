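#' @importFrom data.table as.data.table dcast setcolorder setorderv :=
NULL

#' Proportion of significant tests for a selection of records
#'
#' @param records The `records` data.frame of an [run_experiment()]
#'   result.
#' @param method Method name (or `"valid"` for the uncontaminated
#'   pairs).
#' @param approach Optional approach filter (`"tails"`/`"overlap"`).
#' @param diff Optional difference-level filter (ms).
#' @return The mean of the significance indicator over matching rows.
#' @export
significance_proportion <- function(records, method, approach = NULL, diff = NULL) {
  sel <- records$method == method
  if (!is.null(approach)) sel <- sel & records$approach == approach
  if (!is.null(diff)) sel <- sel & records$diff %in% diff
  if (!any(sel)) stop("no records match the selection")
  mean(records$significant[sel])
}

#' Bias of each exclusion method
#'
#' For every method x approach x difference cell, computes the
#' proportion of significant t-tests and its deviation from the
#' proportion observed on the matched uncontaminated ("valid") pairs:
#' `bias(m | diff) = p_sign(m | diff) - p_sign(valid | diff)`. A
#' positive bias means the method produced significant differences that
#' the valid data did not show (Type-I direction); a negative bias
#' means it concealed differences present in the valid data (Type-II
#' direction).
#'
#' @param records The `records` data.frame of an [run_experiment()]
#'   result; every (iteration, approach) block must contain one row per
#'   method plus one `"valid"` row.
#' @return An object of class `bias_summary`: list with
#'   \describe{
#'     \item{by_diff}{data.table of `p_sign`, `p_sign_valid` and `bias`
#'       per method x approach x diff (the curves behind the bias
#'       figures; the `"valid"` rows carry bias 0).}
#'     \item{table}{data.table with one row per method: mean bias per
#'       approach and the unweighted cross-approach mean, ordered by
#'       decreasing absolute cross-approach bias.}
#'   }
#' @export
compute_bias <- function(records) {
  significant <- p_sign <- p_sign_valid <- bias <- method <- NULL  # NSE notes
  dt <- data.table::as.data.table(records)
  if (!any(dt$method == "valid"))
    stop("records contain no 'valid' reference rows")
  psign <- dt[, list(p_sign = mean(significant)),
              by = c("approach", "diff", "method")]
  valid <- psign[method == "valid",
                 list(approach = approach, diff = diff, p_sign_valid = p_sign)]
  by_diff <- merge(psign, valid, by = c("approach", "diff"))
  by_diff[, bias := p_sign - p_sign_valid]
  data.table::setorderv(by_diff, c("approach", "method", "diff"))

  per <- by_diff[method != "valid",
                 list(bias = mean(bias)), by = c("method", "approach")]
  tab <- data.table::dcast(per, method ~ approach, value.var = "bias")
  app_cols <- setdiff(names(tab), "method")
  tab[, mean := rowMeans(.SD), .SDcols = app_cols]
  data.table::setcolorder(tab, c("method", "mean", app_cols))
  data.table::setorderv(tab, "mean")
  tab <- tab[order(-abs(tab$mean))]
  structure(list(by_diff = by_diff[], table = tab[]), class = "bias_summary")
}

#' @export
print.bias_summary <- function(x, ...) {
  cat("Mean bias of significant-test proportion per exclusion method\n")
  cat("(positive = Type-I direction, negative = Type-II direction)\n\n")
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Descriptive statistics of the simulated samples
#'
#' Summarises the per-sample means, SDs, trial numbers and skewness of
#' valid and contaminated samples per contamination approach: for each
#' per-sample statistic, its mean, SD, minimum and maximum over all
#' samples.
#'
#' @param samples The `samples` data.frame of an [run_experiment()]
#'   result.
#' @return A data.frame with columns `approach`, `sample`
#'   (valid/contaminated), `statistic` (mean/sd/n/skewness), `mean`,
#'   `sd`, `min`, `max`.
#' @export
descriptive_stats <- function(samples) {
  dt <- data.table::as.data.table(samples)
  summarise <- function(v) list(mean = mean(v, na.rm = TRUE),
                                sd = stats::sd(v, na.rm = TRUE),
                                min = min(v, na.rm = TRUE),
                                max = max(v, na.rm = TRUE))
  blocks <- list(
    list(sample = "valid", statistic = "mean", col = "valid_mean"),
    list(sample = "valid", statistic = "sd", col = "valid_sd"),
    list(sample = "valid", statistic = "n", col = "n"),
    list(sample = "valid", statistic = "skewness", col = "valid_skew"),
    list(sample = "contaminated", statistic = "mean", col = "cont_mean"),
    list(sample = "contaminated", statistic = "sd", col = "cont_sd"),
    list(sample = "contaminated", statistic = "skewness", col = "cont_skew")
  )
  out <- do.call(rbind, lapply(unique(dt$approach), function(a) {
    sub <- dt[dt$approach == a]
    do.call(rbind, lapply(blocks, function(b) {
      s <- summarise(sub[[b$col]])
      data.frame(approach = a, sample = b$sample, statistic = b$statistic,
                 mean = s$mean, sd = s$sd, min = s$min, max = s$max,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Linear regression predicting the t-values
#'
#' Ordinary least squares of the per-iteration t-value on the
#' population difference, the exclusion method (factor with reference
#' level `"no"`), and the post-exclusion SD and sample size averaged
#' across the two conditions. The `"valid"` pseudo-method rows are not
#' part of the model; rows whose test was undefined are dropped. Each
#' method coefficient states how that method shifts the expected
#' t-value relative to no exclusion.
#'
#' @param records The `records` data.frame of an [run_experiment()]
#'   result covering at least two methods.
#' @return An object of class `rt_regression`: list with
#'   `coefficients` (data.frame of term, estimate, SE, t-value) and
#'   `fit` (the underlying `lm`).
#' @export
regress_t_values <- function(records) {
  d <- records[records$method != "valid" & is.finite(records$t), ]
  if (length(unique(d$method)) < 2L)
    stop("regression needs records from at least two methods")
  lev <- intersect(c("no", .method_names), unique(d$method))
  if (!"no" %in% lev) lev <- unique(d$method)
  d$method <- factor(d$method, levels = lev)
  d$mean_sd <- (d$sd1 + d$sd2) / 2
  d$mean_n <- (d$n1 + d$n2) / 2
  fit <- stats::lm(t ~ diff + mean_sd + mean_n + method, data = d)
  if (anyNA(stats::coef(fit)))
    stop("rank-deficient design; check that predictors vary")
  cf <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(cf), estimate = cf[, 1L],
                      se = cf[, 2L], t_value = cf[, 3L],
                      stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  coefs$term <- sub("^method", "", coefs$term)
  structure(list(coefficients = coefs, fit = fit), class = "rt_regression")
}

#' @export
print.rt_regression <- function(x, ...) {
  cat("OLS model of t-values on difference, variability, sample size and method\n\n")
  out <- x$coefficients
  out$estimate <- signif(out$estimate, 4)
  out$se <- signif(out$se, 3)
  out$t_value <- round(out$t_value, 1)
  print(out, row.names = FALSE)
  invisible(x)
}

#' Correlation between |bias| and excluded proportion
#'
#' Pearson correlation, per contamination approach, between the
#' absolute bias of a method and the mean proportion of RTs it
#' excluded. The `"no"` method is left out (its bias dominates the
#' correlation while it excludes nothing). Because the aggregation unit
#' is a design choice, the correlation is computed both over
#' method x difference cells and over per-method means.
#'
#' @param bias A [compute_bias()] result.
#' @param records The matching `records` data.frame.
#' @return A data.frame with columns `approach`, `unit`
#'   (`"method_diff"` or `"method"`) and `r`.
#' @export
bias_exclusion_correlation <- function(bias, records) {
  prop_excl_low <- prop_excl_high <- NULL  # NSE notes
  stopifnot(inherits(bias, "bias_summary"))
  dt <- data.table::as.data.table(records)
  excl <- dt[!dt$method %in% c("valid", "no"),
             list(prop_excluded = mean(prop_excl_low + prop_excl_high)),
             by = c("approach", "diff", "method")]
  bd <- as.data.frame(bias$by_diff)
  bd <- bd[!bd$method %in% c("valid", "no"), ]
  cells <- merge(as.data.table(bd), excl, by = c("approach", "diff", "method"))
  out <- do.call(rbind, lapply(unique(cells$approach), function(a) {
    sub <- cells[cells$approach == a]
    if (nrow(sub) < 3L) stop("fewer than 3 cells; correlation undefined")
    if (stats::sd(sub$prop_excluded) == 0 || stats::sd(abs(sub$bias)) == 0)
      stop("zero variance in bias or excluded proportion; correlation undefined")
    per_m <- sub[, list(bias = mean(abs(bias)), prop = mean(prop_excluded)),
                 by = "method"]
    data.frame(approach = a,
               unit = c("method_diff", "method"),
               r = c(stats::cor(abs(sub$bias), sub$prop_excluded),
                     if (nrow(per_m) >= 3L && stats::sd(per_m$prop) > 0)
                       stats::cor(per_m$bias, per_m$prop) else NA_real_),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
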