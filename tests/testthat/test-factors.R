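test_that("z-scoring uses the population-SD convention", {
  z <- zscore_table(data.frame(x = c(1, 2, 3)))
  expect_equal(z$x, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  withr::with_seed(1, df <- data.frame(a = rnorm(50), b = runif(50)))
  z2 <- zscore_table(df)
  for (col in z2) {
    expect_lt(abs(mean(col)), 1e-10)
    expect_lt(abs(sqrt(mean((col - mean(col))^2)) - 1), 1e-10)
  }
  expect_error(zscore_table(data.frame(ok = 1:3, flat = rep(2, 3))), "flat")
})

test_that("PCA eigenstructure behaves on white and rank-1 data", {
  withr::with_seed(2, white <- as.data.frame(matrix(rnorm(2000 * 5), 2000, 5)))
  ev <- battery_pca(zscore_table(white))
  expect_true(all(abs(ev$eigenvalues - 1) < 0.2))
  # noiseless rank-1 table: first eigenvalue = n_variables, rest 0
  withr::with_seed(3, f <- rnorm(40))
  rank1 <- data.frame(v1 = 2 * f, v2 = -f, v3 = 0.5 * f)
  ev1 <- battery_pca(zscore_table(rank1))
  expect_equal(ev1$eigenvalues[1], 3, tolerance = 1e-8)
  expect_true(all(abs(ev1$eigenvalues[-1]) < 1e-8))
})

test_that("eigenvalues match a characteristic-polynomial oracle and conserve variance", {
  withr::with_seed(4, toy <- as.data.frame(matrix(rnorm(30 * 6), 30, 6)))
  Z <- zscore_table(toy)
  ev <- battery_pca(Z)
  expect_equal(ev$eigenvalues, oracle_eigenvalues(cor(as.matrix(Z))),
    tolerance = 1e-6
  )
  expect_lt(abs(sum(ev$eigenvalues) - 6), 1e-8)
  # loadings are eigenvectors scaled by sqrt(eigenvalue): squared column
  # sums give the eigenvalues back
  expect_equal(unname(colSums(ev$loadings^2)), ev$eigenvalues, tolerance = 1e-10)
})

test_that("varimax leaves perfect simple structure alone and preserves communality", {
  L <- rbind(
    c(0.9, 0), c(0.8, 0), c(0.7, 0),
    c(0, 0.9), c(0, 0.8), c(0, 0.6)
  )
  rot <- rotate_varimax(L, normalize = FALSE)
  # identity up to column sign/permutation
  agreement <- abs(t(rot$loadings) %*% L) / outer(
    sqrt(colSums(rot$loadings^2)), sqrt(colSums(L^2))
  )
  expect_equal(sort(apply(agreement, 1, max)), c(1, 1), tolerance = 1e-6)
  withr::with_seed(5, L2 <- matrix(rnorm(12), 6, 2))
  rot2 <- rotate_varimax(L2, normalize = TRUE)
  expect_lt(max(abs(rowSums(rot2$loadings^2) - rowSums(L2^2))), 1e-8)
  expect_lt(max(abs(crossprod(rot2$rotmat) - diag(2))), 1e-8)
  # single factor: nothing to rotate
  one <- rotate_varimax(L[, 1, drop = FALSE])
  expect_identical(one$rotmat, diag(1))
})

test_that("the 2-factor varimax solution matches a grid search over the rotation angle", {
  withr::with_seed(6, L <- matrix(rnorm(10), 5, 2))
  rot <- rotate_varimax(L, normalize = FALSE, eps = 1e-10)
  thetas <- seq(0, pi / 2, by = 1e-4)
  crits <- vapply(thetas, function(th) {
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    oracle_varimax_criterion(L %*% R)
  }, numeric(1))
  expect_equal(varimax_criterion(rot$loadings), max(crits), tolerance = 1e-6)
})

test_that("varimax reaches the same criterion from random orthogonal starts", {
  withr::with_seed(7, {
    L <- cbind(c(0.8, 0.7, 0.1, 0.2, 0), c(0.1, 0, 0.9, 0.6, 0.5))
    ref <- varimax_criterion(rotate_varimax(L, normalize = FALSE, eps = 1e-12)$loadings)
    for (i in 1:50) {
      Q <- qr.Q(qr(matrix(rnorm(4), 2, 2)))
      crit <- varimax_criterion(
        rotate_varimax(L %*% Q, normalize = FALSE, eps = 1e-12)$loadings
      )
      expect_lt(abs(crit - ref), 1e-6)
    }
  })
})

test_that("parallel analysis recovers the planted number of factors", {
  strong <- function(k, n, seed) {
    withr::with_seed(seed, {
      lat <- matrix(rnorm(n * k), n, k)
      L <- matrix(0, 3 * k, k)
      for (j in seq_len(k)) L[(3 * j - 2):(3 * j), j] <- 0.8
      as.data.frame(lat %*% t(L) + 0.6 * matrix(rnorm(n * 3 * k), n))
    })
  }
  pa3 <- parallel_analysis(zscore_table(strong(3, 500, 8)), seed = 9)
  expect_identical(pa3$n_factors, 3L)
  pa1 <- parallel_analysis(zscore_table(strong(1, 500, 10)), seed = 11)
  expect_identical(pa1$n_factors, 1L)
  expect_error(parallel_analysis(strong(1, 50, 1), n_iter = 10), "n_iter")
})

test_that("parallel analysis retains nothing on pure noise in most seeds", {
  hits <- vapply(1:20, function(i) {
    withr::with_seed(100 + i, {
      noise <- as.data.frame(matrix(rnorm(300 * 6), 300, 6))
    })
    parallel_analysis(zscore_table(noise), n_iter = 100, seed = 200 + i)$n_factors
  }, integer(1))
  expect_gte(mean(hits == 0L), 0.9)
})

test_that("regression scores recover planted latents on noiseless data", {
  withr::with_seed(12, {
    lat <- matrix(rnorm(100 * 2), 100, 2)
    L <- cbind(c(0.9, 0.8, 0.7, 0, 0, 0), c(0, 0, 0, 0.9, 0.8, 0.7))
    obs <- as.data.frame(lat %*% t(L))
  })
  names(obs) <- paste0("v", 1:6)
  Z <- zscore_table(obs)
  fm <- fit_factor_model(obs, n_factors = 2)
  # recovery is defined up to sign/rotation of the factor basis: the score
  # subspace must coincide with the latent subspace (canonical correlations)
  cc <- stats::cancor(fm$scores, lat)$cor
  expect_true(all(cc >= 0.999))
  # and each rotated factor is dominated by one latent
  cong <- abs(cor(fm$scores, lat))
  expect_true(all(apply(cong, 2, max) >= 0.9))
})

test_that("factor scores equal the Thurstone closed form on noisy data", {
  withr::with_seed(16, {
    lat <- matrix(rnorm(80 * 2), 80, 2)
    L <- cbind(c(0.8, 0.7, 0, 0), c(0, 0, 0.8, 0.7))
    obs <- as.data.frame(lat %*% t(L) + 0.5 * matrix(rnorm(80 * 4), 80))
  })
  names(obs) <- paste0("v", 1:4)
  Z <- zscore_table(obs)
  fm <- fit_factor_model(obs, n_factors = 2)
  Zm <- as.matrix(Z)
  scores <- factor_scores(Z, fm$loadings)
  expect_equal(unname(scores), unname(Zm %*% solve(cor(Zm), fm$loadings)),
    tolerance = 1e-8
  )
  expect_equal(unname(fm$scores), unname(scores), tolerance = 1e-10)
  dup <- fm$loadings[, c(1, 1)]
  expect_error(factor_scores(Z, dup), "collinear")
})

test_that("planted 3-factor loadings are recovered with high congruence", {
  cohort <- simulate_cohort(200, seed = 13)
  planted <- attr(cohort, "loadings")
  fm <- fit_factor_model(cohort[rownames(planted)], n_factors = 3, seed = 14)
  cong <- match_congruence(fm$loadings, planted)
  expect_true(all(cong >= 0.95))
})

test_that("ceiling-effect columns are dropped with a warning", {
  withr::with_seed(15, df <- data.frame(
    ok1 = rnorm(60), ok2 = rnorm(60), ok3 = rnorm(60),
    alliteration = c(rep(10, 58), 9, 8)
  ))
  expect_warning(fm <- fit_factor_model(df, n_factors = 1), "alliteration")
  expect_identical(fm$dropped, "alliteration")
  expect_false("alliteration" %in% rownames(fm$loadings))
  g <- glance(fm)
  expect_identical(g$n_dropped, 1L)
  td <- tidy(fm)
  expect_named(td, c("variable", "factor", "loading"))
})

test_that("OECD equivalization follows the couple-normalized modified scale", {
  # childless couple: divisor exactly 1, income unchanged
  expect_equal(equivalize_income(30000, 2, list(integer())), 30000)
  # single adult with children aged 5 and 8: divisor 0.67 + 0.20 + 0.20
  expect_equal(equivalize_income(30000, 1, list(c(5, 8))), 30000 / 1.07)
  # couple plus one 15-year-old: divisor 0.67 + 0.33 + 0.33
  expect_equal(equivalize_income(30000, 2, list(15)), 30000 / 1.33)
  expect_error(equivalize_income(-5, 2, list(integer())), "positive")
  expect_error(equivalize_income(100, 0, list(integer())), "adult")
  expect_error(oecd_scale(first_adult = 0.1), "largest")
})

test_that("the poverty line is inclusive at 60% of the reference median", {
  expect_false(poverty_flag(31876, 31876))
  expect_true(poverty_flag(0.6 * 31876, 31876))
  expect_true(poverty_flag(19000, 31876)) # threshold 19125.6
  expect_false(poverty_flag(19200, 31876))
  expect_error(poverty_flag(-1, 31876), "positive")
})
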