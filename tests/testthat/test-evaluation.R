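# hand-built records table with the columns run_experiment() produces
toy_records <- function(sig_by_method, diff = 0, approach = "tails") {
  n_iter <- length(sig_by_method[[1]])
  do.call(rbind, lapply(names(sig_by_method), function(m) {
    data.frame(iteration = seq_len(n_iter), approach = approach, diff = diff,
               method = m, t = 1, p = 0.5, significant = sig_by_method[[m]],
               n1 = 50L, n2 = 50L, sd1 = 170, sd2 = 170,
               prop_excl_low = ifelse(m %in% c("valid", "no"), 0, 0.02),
               prop_excl_high = ifelse(m %in% c("valid", "no"), 0, 0.03),
               stringsAsFactors = FALSE)
  }))
}

test_that("significance_proportion counts matching records", {
  rec <- toy_records(list(valid = rep(TRUE, 10)))
  expect_equal(significance_proportion(rec, "valid"), 1)
  rec2 <- toy_records(list(valid = rep(c(TRUE, FALSE, FALSE), c(3, 7, 0))))
  expect_equal(significance_proportion(rec2, "valid"), 0.3)
  expect_error(significance_proportion(rec, "2sd"), "no records match")
})

test_that("compute_bias is the significance-rate gap against valid pairs", {
  rec <- toy_records(list(
    valid = rep(c(TRUE, FALSE), c(5, 5)),    # p_sign 0.5
    no = rep(c(TRUE, FALSE), c(6, 4)),       # p_sign 0.6 -> bias 0.10
    q10 = rep(c(TRUE, FALSE), c(2, 8))       # p_sign 0.2 -> bias -0.30
  ))
  b <- compute_bias(rec)
  bd <- as.data.frame(b$by_diff)
  expect_equal(bd$bias[bd$method == "valid"], 0)
  expect_equal(bd$bias[bd$method == "no"], 0.10)
  expect_equal(b$table$mean[b$table$method == "q10"], -0.30)
  # table is ordered by decreasing absolute cross-approach bias
  expect_identical(b$table$method, c("q10", "no"))

  expect_error(compute_bias(rec[rec$method != "valid", ]), "no 'valid'")
})

test_that("the t-value regression recovers planted coefficients", {
  set.seed(61)
  n <- 4000
  methods <- c("no", "2sd", "MAD")
  method_effect <- c(no = 0, `2sd` = 0.7, MAD = 1.2)
  d <- data.frame(
    iteration = seq_len(n), approach = "tails",
    diff = sample(0:100, n, replace = TRUE),
    method = sample(methods, n, replace = TRUE),
    n1 = sample(20:100, n, replace = TRUE),
    sd1 = runif(n, 100, 250), p = 0.5, significant = FALSE,
    prop_excl_low = 0, prop_excl_high = 0,
    stringsAsFactors = FALSE
  )
  d$n2 <- d$n1
  d$sd2 <- d$sd1
  beta <- c(intercept = -1, diff = 0.033, sd = -0.002, n = 0.014)
  d$t <- beta["intercept"] + beta["diff"] * d$diff + beta["sd"] * d$sd1 +
    beta["n"] * d$n1 + method_effect[d$method] + rnorm(n, 0, 0.5)
  # the regression must see one valid row to mimic real records; add it
  valid_rows <- d[1:2, ]
  valid_rows$method <- "valid"
  fit <- regress_t_values(rbind(d, valid_rows))
  cf <- fit$coefficients
  for (pair in list(c("(Intercept)", beta[["intercept"]]),
                    c("diff", beta[["diff"]]),
                    c("mean_sd", beta[["sd"]]),
                    c("mean_n", beta[["n"]]),
                    c("2sd", method_effect[["2sd"]]),
                    c("MAD", method_effect[["MAD"]]))) {
    row <- cf[cf$term == pair[1], ]
    expect_lt(abs(row$estimate - as.numeric(pair[2])), 3 * row$se)
  }
})

test_that("identical t-values across methods give near-zero method coefficients", {
  set.seed(62)
  n <- 600
  half_n <- sample(20:100, n / 2, replace = TRUE)
  half_sd <- runif(n / 2, 120, 220)
  base <- data.frame(
    iteration = rep(1:(n / 2), 2), approach = "tails",
    diff = rep(sample(0:100, n / 2, replace = TRUE), 2),
    method = rep(c("no", "2sd"), each = n / 2),
    n1 = rep(half_n, 2), n2 = rep(half_n, 2),
    sd1 = rep(half_sd, 2), sd2 = rep(half_sd, 2),
    p = 0.5, significant = FALSE,
    prop_excl_low = 0, prop_excl_high = 0, stringsAsFactors = FALSE
  )
  base$t <- 0.03 * base$diff + rep(rnorm(n / 2, 0, 0.2), 2)
  cf <- regress_t_values(base)$coefficients
  expect_lt(abs(cf$estimate[cf$term == "2sd"]), 0.01)
})

test_that("regression demands at least two methods and full rank", {
  rec <- toy_records(list(valid = rep(TRUE, 5), no = rep(TRUE, 5)))
  expect_error(regress_t_values(rec), "at least two methods")
})

test_that("|bias| vs excluded-proportion correlation behaves on toy tables", {
  # three methods whose |bias| is exactly proportional to their excluded share
  mk <- function(p_excl, p_sign, m) {
    sig <- rep(c(TRUE, FALSE), c(round(20 * p_sign), 20 - round(20 * p_sign)))
    data.frame(iteration = 1:20, approach = "tails", diff = 0, method = m,
               t = 1, p = 0.5, significant = sig, n1 = 50L, n2 = 50L,
               sd1 = 170, sd2 = 170, prop_excl_low = p_excl / 2,
               prop_excl_high = p_excl / 2, stringsAsFactors = FALSE)
  }
  rec <- rbind(mk(0, 0.5, "valid"), mk(0.02, 0.6, "2sd"),
               mk(0.04, 0.7, "q10"), mk(0.08, 0.9, "MAD"))
  b <- compute_bias(rec)
  r <- bias_exclusion_correlation(b, rec)
  expect_equal(r$r[r$unit == "method"], 1, tolerance = 1e-9)

  # zero variance in the excluded proportion -> undefined
  rec2 <- rbind(mk(0, 0.5, "valid"), mk(0.02, 0.6, "2sd"),
                mk(0.02, 0.7, "q10"), mk(0.02, 0.9, "MAD"))
  expect_error(bias_exclusion_correlation(compute_bias(rec2), rec2),
               "zero variance")
})

test_that("run_experiment is deterministic and structurally complete", {
  cfg <- sim_config(diffs = c(0, 40), reps = 15, seed = 77,
                    approaches = "tails", methods = c("no", "2sd", "MAD"))
  a <- run_experiment(cfg)
  b <- run_experiment(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$samples, b$samples)

  rec <- a$records
  expect_equal(nrow(rec), 2 * 15 * (3 + 1))
  per_block <- table(rec$iteration)
  expect_true(all(per_block == 4))
  expect_true(all(tapply(rec$method == "valid", rec$iteration, sum) == 1))
  expect_true(all(rec$n1[rec$method == "valid"] >= 20))
  expect_true(all(rec$p >= 0 & rec$p <= 1, na.rm = TRUE))
  expect_identical(rec$significant, !is.na(rec$p) & rec$p < 0.05)
})

test_that("descriptive statistics summarise per-sample moments", {
  cfg <- sim_config(diffs = 0, reps = 30, seed = 78, approaches = "overlap",
                    methods = "no")
  res <- run_experiment(cfg)
  de <- res$descriptives
  expect_setequal(unique(de$statistic), c("mean", "sd", "n", "skewness"))
  vm <- de[de$sample == "valid" & de$statistic == "mean", ]
  expect_true(vm$min <= vm$mean && vm$mean <= vm$max)
  n_row <- de[de$sample == "valid" & de$statistic == "n", ]
  expect_true(n_row$min >= 20 && n_row$max <= 100)
  # contaminated SD exceeds valid SD on average
  expect_gt(de$mean[de$sample == "contaminated" & de$statistic == "sd"],
            de$mean[de$sample == "valid" & de$statistic == "sd"])
})
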