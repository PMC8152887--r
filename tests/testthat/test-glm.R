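test_that("the reference cohort yields a 71 x 8 design with standardized covariates", {
  cohort <- simulate_cohort(71, seed = 1)
  covariates <- build_covariate_table(cohort, seed = 2)
  design <- build_design_matrix(covariates, setdiff(names(covariates), "subject_id"))
  expect_identical(dim(design$X), c(71L, 8L))
  expect_true(all(design$X[, 1] == 1))
  expect_identical(design$regressor_names[1], "intercept")
  for (j in 2:8) {
    col <- design$X[, j]
    expect_lt(abs(mean(col)), 1e-10)
    expect_lt(abs(sqrt(mean((col - mean(col))^2)) - 1), 1e-10)
  }
})

test_that("degenerate designs are caught", {
  # intercept-only design for 3 subjects
  d0 <- build_design_matrix(data.frame(subject_id = letters[1:3]), character())
  expect_identical(dim(d0$X), c(3L, 1L))
  expect_true(all(d0$X == 1))
  # exact collinearity is reported with the offending column
  withr::with_seed(3, df <- data.frame(a = rnorm(10)))
  df$b <- df$a
  expect_error(build_design_matrix(df, c("a", "b")), "collinear")
  expect_error(build_design_matrix(df, c("a", "missing_col")), "missing_col")
  df$c <- c(NA, rnorm(9))
  expect_error(build_design_matrix(df, c("a", "c")), "missing values")
})

test_that("an intercept-only fit reproduces the one-sample t statistic", {
  withr::with_seed(4, {
    cf <- as_contrast_field(array(rnorm(12 * 3 * 5), c(12, 3, 5)), times_ms = 1:5)
  })
  design <- build_design_matrix(data.frame(subject_id = cf$subjects), character())
  fit <- fit_ols(design, cf)
  expect_identical(fit$dof, 11L)
  for (s in 1:3) {
    for (k in 1:5) {
      y <- cf$data[, s, k]
      expect_equal(fit$betas[1, s, k], mean(y), tolerance = 1e-12)
      expect_equal(fit$t_values[1, s, k], mean(y) / (sd(y) / sqrt(12)),
        tolerance = 1e-10
      )
    }
  }
})

test_that("vectorized OLS matches the per-point normal-equation oracle", {
  withr::with_seed(5, {
    covs <- data.frame(a = rnorm(8), b = rnorm(8))
    cf <- as_contrast_field(array(rnorm(8 * 3 * 4), c(8, 3, 4)), times_ms = 1:4)
  })
  design <- build_design_matrix(covs, c("a", "b"))
  fit <- fit_ols(design, cf)
  for (s in 1:3) {
    for (k in 1:4) {
      oracle <- oracle_ols_point(design$X, cf$data[, s, k])
      expect_equal(unname(fit$betas[, s, k]), oracle$beta, tolerance = 1e-10)
      expect_equal(unname(fit$standard_errors[, s, k]), unname(oracle$se),
        tolerance = 1e-10
      )
      expect_equal(unname(fit$t_values[, s, k]), oracle$t, tolerance = 1e-10)
    }
  }
  expect_true(all(abs(fit$t_values - fit$betas / fit$standard_errors) < 1e-12))
})

test_that("under the null the t map follows Student t with dof n - p", {
  withr::with_seed(6, {
    covs <- data.frame(a = rnorm(20), b = rnorm(20), c = rnorm(20))
    cf <- as_contrast_field(array(rnorm(20 * 10 * 40), c(20, 10, 40)),
      times_ms = seq_len(40)
    )
  })
  design <- build_design_matrix(covs, c("a", "b", "c"))
  fit <- fit_ols(design, cf)
  expect_identical(fit$dof, 16L)
  tpool <- as.numeric(fit$t_values["a", , ])
  ks <- suppressWarnings(stats::ks.test(tpool, stats::pt, df = 16))
  expect_gt(ks$p.value, 0.01)
})

test_that("shifting a covariate before z-scoring changes nothing", {
  withr::with_seed(7, {
    covs <- data.frame(a = rnorm(15), b = rnorm(15))
    cf <- as_contrast_field(array(rnorm(15 * 4 * 6), c(15, 4, 6)), times_ms = 1:6)
  })
  f1 <- fit_ols(build_design_matrix(covs, c("a", "b")), cf)
  covs2 <- covs
  covs2$a <- covs2$a + 1000
  f2 <- fit_ols(build_design_matrix(covs2, c("a", "b")), cf)
  expect_equal(f1$betas, f2$betas, tolerance = 1e-8)
})

test_that("misaligned subjects and saturated designs are rejected", {
  withr::with_seed(8, {
    covs <- data.frame(subject_id = sprintf("sub%03d", 1:10), a = rnorm(10))
    cf <- as_contrast_field(array(rnorm(10 * 2 * 3), c(10, 2, 3)), times_ms = 1:3)
  })
  design <- build_design_matrix(covs, "a")
  cf_bad <- cf
  cf_bad$subjects <- rev(cf$subjects)
  expect_error(fit_ols(design, cf_bad), "misaligned")
  cf_small <- as_contrast_field(cf$data[1:2, , , drop = FALSE], times_ms = 1:3)
  expect_error(fit_ols(design, cf_small), "subjects")
  fit <- fit_ols(design, cf)
  expect_error(t_map(fit, "nope"), "unknown regressor")
  expect_equal(dim(t_map(fit, "a")), c(2L, 3L))
})

test_that("the two-sided critical t at dof 70 rounds to 2", {
  expect_equal(round(critical_t(0.05, 70)), 2)
  expect_equal(critical_t(0.05, 70), qt(0.975, 70))
})
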