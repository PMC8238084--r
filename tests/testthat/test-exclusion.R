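test_that("no-exclusion keeps everything", {
  out <- exclude_none(c(100, 5000, 300))
  expect_true(all(out$kept_mask))
  expect_equal(out$prop_excluded_low, 0)
  expect_equal(out$prop_excluded_high, 0)
})

test_that("a-priori cutoffs drop below 200 ms and above mean + 1000 ms", {
  out <- exclude_cutoff(c(150, 300, 400, 2000))   # mean 712.5, upper 1712.5
  expect_equal(out$upper_threshold, 1712.5)
  expect_identical(out$kept_mask, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(out$prop_excluded_low, 0.25)
  expect_equal(out$prop_excluded_high, 0.25)

  expect_true(all(exclude_cutoff(c(300, 400, 500))$kept_mask))

  out2 <- exclude_cutoff(c(100, 250))             # mean 175, upper 1175
  expect_identical(out2$kept_mask, c(FALSE, TRUE))
})

test_that("SD rules use the sample SD of the input and widen with k", {
  x <- c(300, 320, 340, 360, 380, 400, 2000)
  out2 <- exclude_sd(x, 2)   # upper ~ 1834.9: only 2000 out
  expect_identical(out2$kept_mask, c(rep(TRUE, 6), FALSE))
  expect_equal(out2$upper_threshold, mean(x) + 2 * sd(x))
  out3 <- exclude_sd(x, 3)   # upper ~ 2459.4: nothing out
  expect_true(all(out3$kept_mask))

  expect_true(all(suppressWarnings(exclude_sd(rep(400, 5), 2))$kept_mask))
  expect_warning(exclude_sd(400, 2), "fewer than 2")
})

test_that("Tukey fences use interpolated quartiles and strict comparison", {
  x <- c(100, 200, 300, 400, 500, 600, 700, 5000)
  out <- exclude_tukey(x)     # q1 275, q3 625, fences (-250, 1150)
  expect_equal(out$lower_threshold, -250)
  expect_equal(out$upper_threshold, 1150)
  expect_identical(which(!out$kept_mask), 8L)

  # a value exactly on the fence is kept
  y <- c(x[1:7], 1150)
  expect_true(all(exclude_tukey(y)$kept_mask[8]))

  expect_true(all(exclude_tukey(c(300, 350, 400, 450, 500))$kept_mask))
  expect_warning(exclude_tukey(c(1, 2, 3)), "fewer than 4")
})

test_that("quantile rules exclude strictly outside the interpolated quantiles", {
  x <- seq(100, 2000, by = 100)
  out10 <- exclude_quantile(x, 0.05)   # q0.05 = 195, q0.95 = 1905
  expect_equal(out10$lower_threshold, 195)
  expect_equal(out10$upper_threshold, 1905)
  expect_identical(which(!out10$kept_mask), c(1L, 20L))
  expect_equal(out10$prop_excluded_low + out10$prop_excluded_high, 0.1)

  out05 <- exclude_quantile(x, 0.025)  # 147.5 / 1952.5
  expect_equal(out05$lower_threshold, 147.5)
  expect_identical(which(!out05$kept_mask), c(1L, 20L))
})

test_that("MAD rules: the adjusted constant is stricter", {
  x <- c(235, 300, 320, 340, 360, 380, 400, 2000)
  out <- exclude_mad(x, b = 1.4826)    # MAD 59.30, bounds (201.7, 498.3)
  expect_equal(out$lower_threshold, 350 - 2.5 * 1.4826 * 40)
  expect_identical(which(!out$kept_mask), 8L)

  out_adj <- exclude_mad(x, b = 1.1020)  # MAD 44.08, bounds (239.8, 460.2)
  expect_identical(which(!out_adj$kept_mask), c(1L, 8L))

  expect_warning(out0 <- exclude_mad(rep(350, 6)), "MAD is zero")
  expect_true(all(out0$kept_mask))
})

test_that("transform rule z-scores the square-root range-normalised values", {
  x <- c(100, rep(300, 10), 3000)
  out <- exclude_transform(x)          # z(3000) = 3.00 > 2, z(100) = -1.30
  expect_identical(which(!out$kept_mask), 12L)

  x2 <- c(100, 200, 300, 400, 500, 2000)
  expect_true(all(exclude_transform(x2)$kept_mask))  # z(2000) = 1.79

  expect_warning(out0 <- exclude_transform(rep(400, 5)), "degenerate")
  expect_true(all(out0$kept_mask))
})

test_that("apply_method dispatches to the matching rule", {
  x <- c(300, 320, 340, 360, 380, 400, 2000)
  expect_true(all(apply_method("no", x)$kept_mask))
  expect_identical(apply_method("2sd", x)$kept_mask, exclude_sd(x, 2)$kept_mask)
  expect_identical(apply_method("MAD", x)$kept_mask,
                   exclude_mad(x, b = 1.4826)$kept_mask)
  expect_identical(apply_method("q05", x)$kept_mask,
                   exclude_quantile(x, 0.025)$kept_mask)
  expect_error(apply_method("winsorize", x), "unknown exclusion method")
})

test_that("every rule matches a brute-force oracle on small vectors", {
  methods <- all_method_names()
  grid <- as.matrix(expand.grid(rep(list(seq(100, 600, by = 100)), 4)))
  for (m in methods) {
    for (i in seq_len(nrow(grid))) {
      x <- as.numeric(grid[i, ])
      got <- suppressWarnings(apply_method(m, x))$kept_mask
      expect_identical(got, oracle_mask(m, x))
    }
  }
  set.seed(41)
  for (rep_i in 1:300) {
    n <- sample(4:8, 1)
    x <- runif(n, 100, 600)
    if (rep_i %% 3 == 0) x[sample(n, 1)] <- runif(1, 1500, 6000)  # plant an outlier
    for (m in methods) {
      got <- suppressWarnings(apply_method(m, x))$kept_mask
      expect_identical(got, oracle_mask(m, x))
    }
  }
})

test_that("exclusion sets nest and counts are conserved", {
  set.seed(42)
  for (i in 1:100) {
    x <- sample_exgauss(exg_params(400, 30, 175), sample(20:100, 1))
    m2 <- apply_method("2sd", x)
    m3 <- apply_method("3sd", x)
    expect_true(all(m2$kept_mask[!m3$kept_mask] == FALSE))  # 3sd exclusions within 2sd exclusions
    for (m in all_method_names()) {
      out <- suppressWarnings(apply_method(m, x))
      expect_equal(out$prop_excluded_low + out$prop_excluded_high,
                   1 - mean(out$kept_mask))
      if (!is.na(out$lower_threshold) && !is.na(out$upper_threshold))
        expect_lte(out$lower_threshold, out$upper_threshold)
    }
  }
})
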