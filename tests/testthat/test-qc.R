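test_that("class-specific missingness boundaries are inclusive", {
  # non-xenobiotic missing in exactly 30% of samples -> removed
  v <- matrix(runif(10 * 3, 1, 2), 10, 3)
  v[1:3, 1] <- NA # 30% missing
  v[1:2, 2] <- NA # 20% missing
  m <- make_metab(v, xenobiotic = c(FALSE, FALSE, FALSE))
  out <- apply_missingness_filters(m)
  expect_false("met001" %in% colnames(out$matrix$values))
  expect_true("met002" %in% colnames(out$matrix$values))
  expect_equal(out$report$removed_metabolites$reason, "nonxeno_miss")

  # xenobiotic: 79% retained, 80% removed
  v <- matrix(runif(100 * 2, 1, 2), 100, 2)
  v[1:79, 1] <- NA
  v[1:80, 2] <- NA
  m <- make_metab(v, xenobiotic = c(TRUE, TRUE))
  out <- apply_missingness_filters(m, sample_cut = 1)
  expect_true("met001" %in% colnames(out$matrix$values))
  expect_false("met002" %in% colnames(out$matrix$values))
})

test_that("sample filter and per-cohort re-check use their own denominators", {
  v <- matrix(runif(10 * 5, 1, 2), 10, 5)
  v[1, 1:2] <- NA # sample 1 missing 40% of 5 metabolites -> removed
  m <- make_metab(v)
  out <- apply_missingness_filters(m)
  expect_equal(out$report$removed_samples, "S0001")
  expect_equal(nrow(out$matrix$values), 9)

  # re-check: metabolite missing >= 50% within one cohort only
  v <- matrix(runif(20 * 3, 1, 2), 20, 3)
  v[1:5, 1] <- NA # 50% of cohort A (10 samples), 25% overall
  m <- make_metab(v, cohort = rep(c("A", "B"), each = 10))
  out <- apply_missingness_filters(m, nonxeno_cut = 0.30)
  expect_false("met001" %in% colnames(out$matrix$values))
  expect_true(all(out$report$removed_metabolites$reason == "post_clean_miss"))
  # without the re-check it survives the 30% overall filter
  out2 <- apply_missingness_filters(m, recheck = FALSE)
  expect_true("met001" %in% colnames(out2$matrix$values))
})

test_that("fully observed matrix passes untouched with an empty report", {
  v <- matrix(runif(8 * 4, 1, 2), 8, 4)
  m <- make_metab(v)
  out <- apply_missingness_filters(m)
  expect_identical(out$matrix$values, m$values)
  expect_equal(nrow(out$report$removed_metabolites), 0)
  expect_length(out$report$removed_samples, 0)
})

test_that("zero-IQR removal follows the linear-interpolation quantile rule", {
  v <- cbind(rep(1, 8),                # constant -> IQR 0 -> removed
             c(1, 1, 1, 2, 1, 1, 1, 2), # IQR > 0 under type-7 -> retained
             1:8)                      # plainly varying -> retained
  m <- make_metab(v)
  out <- filter_zero_iqr(m)
  expect_equal(colnames(out$matrix$values), c("met002", "met003"))
  expect_equal(out$report$removed_metabolites$reason, "zero_iqr")
  # {1,1,1,2}: type-7 quantiles give IQR 0.25 (brute-force check)
  x <- c(1, 1, 1, 2)
  expect_equal(unname(quantile(x, 0.75, type = 7) - quantile(x, 0.25, type = 7)),
               0.25)
  m2 <- make_metab(cbind(c(1, 1, 1, 2)))
  expect_equal(ncol(filter_zero_iqr(m2)$matrix$values), 1)
  # fewer than 2 observed values -> treated as zero-IQR
  m3 <- make_metab(cbind(c(1, NA, NA, NA)))
  expect_equal(ncol(filter_zero_iqr(m3)$matrix$values), 0)
  expect_true(filter_zero_iqr(m3)$report$empty_after_filtering)
})

test_that("half-minimum imputation is per cohort and skips xenobiotics", {
  v <- cbind(c(2, 4, NA, 10, 20, NA),
             c(2, 4, NA, 10, 20, NA))
  m <- make_metab(v, xenobiotic = c(FALSE, TRUE),
                  cohort = rep(c("A", "B"), each = 3))
  out <- impute_half_minimum(m)
  expect_equal(out$matrix$values[3, 1], 1)  # half of cohort-A min 2
  expect_equal(out$matrix$values[6, 1], 5)  # half of cohort-B min 10
  expect_true(is.na(out$matrix$values[3, 2])) # xenobiotic untouched
  expect_equal(unname(out$report$imputed_cells["A"]), 1L)
  # identity on complete data
  mc <- make_metab(matrix(runif(6, 1, 2), 3, 2))
  expect_identical(impute_half_minimum(mc)$matrix$values, mc$values)
  # no observed value in a cohort -> error
  mb <- make_metab(cbind(c(NA, NA, 1, 2)), cohort = c("A", "A", "B", "B"))
  expect_error(impute_half_minimum(mb), "no observed values")
})

test_that("log10 transform is exact, guarded, and invertible", {
  m <- make_metab(cbind(c(1, 10, 100)))
  out <- log10_transform(m)
  expect_equal(unname(out$values[, 1]), c(0, 1, 2))
  expect_true(out$log_scale)
  v <- matrix(runif(20, 0.5, 50), 10, 2)
  m2 <- make_metab(v)
  expect_equal(10^log10_transform(m2)$values, m2$values, tolerance = 1e-12)
  m0 <- make_metab(cbind(c(1, 2, 3)))
  m0$values[2, 1] <- 0
  expect_error(log10_transform(m0), "met001")
})

test_that("the QC chain is idempotent, monotone in the cut, and conserving", {
  set.seed(42)
  v <- matrix(10^rnorm(50 * 12), 50, 12)
  v[sample(length(v), 120)] <- NA
  v[, 3] <- 1 # zero-IQR target
  xeno <- rep(c(FALSE, TRUE), 6)
  m <- make_metab(v, xenobiotic = xeno, cohort = rep(c("A", "B"), 25))

  once <- qc_metabolites(m)
  twice <- qc_metabolites(once$matrix)
  expect_identical(twice$matrix$values, once$matrix$values)
  expect_equal(nrow(twice$report$removed_metabolites), 0)

  # conservation: retained + removed = input
  expect_equal(ncol(once$matrix$values) +
                 length(unique(once$report$removed_metabolites$metabolite)),
               ncol(m$values))

  # monotonicity: lowering the non-xenobiotic cut never retains more
  cuts <- c(0.5, 0.3, 0.1, 0.05)
  kept <- sapply(cuts, function(ct) {
    ncol(apply_missingness_filters(m, nonxeno_cut = ct)$matrix$values)
  })
  expect_true(all(diff(kept) <= 0))
})
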