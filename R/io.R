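#' Read a simulation configuration from a YAML file
#'
#' Any field not present in the file takes the study default (see
#' [sim_config()]). Recognised keys: `diffs` (either a list of values
#' or a mapping with `from`/`to`/`by`), `reps`, `approaches`,
#' `methods`, `seed`, `alpha`, `min_n`, `output_dir`.
#'
#' @param path Path to a YAML file; an empty file yields the full
#'   default configuration.
#' @return A [sim_config()].
#' @export
load_config <- function(path) {
  stopifnot(file.exists(path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config file must contain a key-value mapping")
  known <- c("diffs", "reps", "approaches", "methods", "seed", "alpha",
             "min_n", "output_dir")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  if (!is.null(raw$diffs) && is.list(raw$diffs)) {
    g <- raw$diffs
    if (!all(c("from", "to") %in% names(g)))
      stop("malformed 'diffs' grid: need 'from' and 'to' (optional 'by')")
    raw$diffs <- seq(g$from, g$to, by = if (is.null(g$by)) 1 else g$by)
  }
  if (!is.null(raw$approaches)) raw$approaches <- unlist(raw$approaches)
  if (!is.null(raw$methods)) {
    # YAML 1.1 reads a bare `no` as boolean FALSE; it means the method "no"
    raw$methods <- vapply(raw$methods, function(m) {
      if (identical(m, FALSE)) "no" else as.character(m)
    }, character(1), USE.NAMES = FALSE)
  }
  if (!is.null(raw$diffs)) raw$diffs <- unlist(raw$diffs)
  do.call(sim_config, raw)
}

#' Write the experiment result tables to CSV
#'
#' Writes `records.csv` (one row per iteration x approach x method),
#' `bias.csv` (mean bias per method and approach plus the per-diff
#' curves), `descriptives.csv` and `regression.csv` into `dir`
#' (comma-separated, header row, "." decimal, UTF-8).
#'
#' @param result An [run_experiment()] result.
#' @param dir Output directory; created if missing. Defaults to the
#'   configuration's `output_dir`.
#' @return Invisibly, the paths written.
#' @export
write_experiment <- function(result, dir = result$config$output_dir) {
  stopifnot(inherits(result, "rt_experiment"))
  if (is.null(dir)) stop("no output directory given")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(x, name) {
    p <- file.path(dir, name)
    utils::write.csv(x, p, row.names = FALSE, fileEncoding = "UTF-8")
    paths <<- c(paths, p)
  }
  wr(result$records, "records.csv")
  bias_out <- merge(as.data.frame(result$bias$by_diff),
                    as.data.frame(result$bias$table)[, c("method", "mean")],
                    by = "method", all.x = TRUE)
  names(bias_out)[names(bias_out) == "mean"] <- "mean_bias_cross_approach"
  wr(bias_out[order(bias_out$approach, bias_out$method, bias_out$diff), ],
     "bias.csv")
  wr(result$descriptives, "descriptives.csv")
  if (!is.null(result$regression)) wr(result$regression$coefficients, "regression.csv")
  invisible(paths)
}

#' Apply an exclusion method to an empirical RT table
#'
#' Applied mode: takes a long-format table of empirical RTs and applies
#' one exclusion method within each condition separately (thresholds
#' are computed per condition, exactly as the simulation applies the
#' rules to each condition's sample). Each row is annotated with a
#' kept/excluded flag and a tail label, and a per-condition report
#' gives the proportions excluded at the low and high tail -- the
#' numbers a study should report alongside its exclusion rule.
#'
#' @param table A data.frame of empirical RTs.
#' @param method One of the ten method names (see
#'   [exclusion_methods()]).
#' @param id_col,condition_col,rt_col Column names for the unit
#'   identifier, the condition label and the RT in ms (defaults `"id"`,
#'   `"condition"`, `"rt"`).
#' @return A list of class `rt_exclusion_report` with `data` (the
#'   input plus `kept` and `tail` columns) and `report` (per
#'   condition: n, proportions excluded low/high/total).
#' @examples
#' tab <- data.frame(id = 1, condition = rep(c("a", "b"), each = 4),
#'                   rt = c(300, 350, 400, 2500, 310, 330, 360, 380))
#' exclude_table(tab, "cutoff")
#' @export
exclude_table <- function(table, method, id_col = "id",
                          condition_col = "condition", rt_col = "rt") {
  stopifnot(is.data.frame(table))
  for (col in c(id_col, condition_col, rt_col))
    if (!col %in% names(table)) stop(sprintf("column '%s' not found", col))
  rt <- table[[rt_col]]
  if (!is.numeric(rt) || any(!is.finite(rt)) || any(rt <= 0))
    stop("RT column must be positive finite numbers (ms)")

  kept <- logical(nrow(table))
  tail <- rep("none", nrow(table))
  conds <- unique(table[[condition_col]])
  report <- do.call(rbind, lapply(conds, function(cond) {
    idx <- which(table[[condition_col]] == cond)
    x <- rt[idx]
    if (length(x) == 1L && method != "no")
      warning(sprintf("condition '%s' has a single row; nothing excluded", cond))
    out <- suppressWarnings(apply_method(method, x))
    kept[idx] <<- out$kept_mask
    tc <- tail_counts(x, out$kept_mask)
    if (any(out$kept_mask)) {
      tail[idx[!out$kept_mask & x < min(x[out$kept_mask])]] <<- "low"
      tail[idx[!out$kept_mask & x > max(x[out$kept_mask])]] <<- "high"
    } else {
      tail[idx] <<- ifelse(x < 200, "low", "high")
    }
    data.frame(condition = cond, n = length(x),
               prop_excluded_low = tc[1L] / length(x),
               prop_excluded_high = tc[2L] / length(x),
               prop_excluded = (tc[1L] + tc[2L]) / length(x),
               stringsAsFactors = FALSE)
  }))
  rownames(report) <- NULL
  data <- table
  data$kept <- kept
  data$tail <- tail
  structure(list(method = method, data = data, report = report),
            class = "rt_exclusion_report")
}

#' @export
print.rt_exclusion_report <- function(x, ...) {
  cat(sprintf("Exclusion report, method '%s' (applied per condition)\n\n", x$method))
  print(x$report, row.names = FALSE, digits = 3)
  invisible(x)
}
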