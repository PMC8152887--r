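grid_adj <- function(n) build_sensor_array(n, "grid")$adjacency

test_that("spatio-temporal neighbourhoods follow the space-or-time rule", {
  # isolated sensor (no spatial neighbours), interior timepoint: 2 neighbours
  iso <- matrix(FALSE, 3, 3)
  nb <- spatiotemporal_neighbors(2, 5, iso, 10)
  expect_identical(nrow(nb), 2L)
  expect_setequal(nb$timepoint, c(4L, 6L))
  # sensor with 3 spatial neighbours at the first timepoint: 3 + 1
  adj <- matrix(FALSE, 4, 4)
  adj[1, 2:4] <- adj[2:4, 1] <- TRUE
  nb2 <- spatiotemporal_neighbors(1, 1, adj, 6)
  expect_identical(nrow(nb2), 4L)
  # exhaustive pairwise check on a random 5-sensor x 6-time grid
  withr::with_seed(1, {
    radj <- matrix(runif(25) < 0.4, 5, 5)
    radj <- radj | t(radj)
    diag(radj) <- FALSE
  })
  for (s in 1:5) {
    for (tt in 1:6) {
      got <- spatiotemporal_neighbors(s, tt, radj, 6)
      expected <- list()
      for (s2 in 1:5) {
        for (t2 in 1:6) {
          is_nb <- (t2 == tt && radj[s, s2]) || (s2 == s && abs(t2 - tt) == 1)
          if (is_nb) expected[[length(expected) + 1]] <- c(s2, t2)
        }
      }
      got_keys <- paste(got$sensor, got$timepoint)
      exp_keys <- vapply(expected, function(p) paste(p[1], p[2]), "")
      expect_setequal(got_keys, exp_keys)
    }
  }
})

test_that("cluster formation handles empty and singleton maps", {
  cfg <- cluster_config(4, 100)
  adj <- grid_adj(4)
  flat <- matrix(1, 4, 5)
  expect_identical(nrow(form_clusters(flat, adj, cfg)), 0L)
  single <- matrix(0, 4, 5)
  single[2, 3] <- 5
  cl <- form_clusters(single, adj, cfg)
  expect_identical(nrow(cl), 1L)
  expect_equal(cl$statistic, 5)
  expect_identical(cl$n_sensors, 1L)
  expect_identical(cl$onset_idx, 3L)
  expect_identical(cl$offset_idx, 3L)
  expect_error(form_clusters(matrix(c(1, NA), 1, 2), matrix(FALSE, 1, 1), cfg), "finite")
})

test_that("cluster formation matches the flood-fill oracle on random maps", {
  cfg <- cluster_config(2.8, 100)
  adj <- grid_adj(6)
  withr::with_seed(2, {
    for (i in 1:200) {
      tm <- matrix(rnorm(48, sd = 2), 6, 8)
      got <- form_clusters(tm, adj, cfg)
      expected <- oracle_clusters(tm, adj, 2.8)
      expect_identical(nrow(got), length(expected))
      got_keys <- sort(unname(vapply(got$members, member_key, "")))
      exp_keys <- sort(unname(vapply(expected, member_key, "")))
      expect_identical(got_keys, exp_keys)
      # statistics agree per matched member set
      exp_stats <- unname(vapply(expected, function(m) mean(tm[m]), numeric(1)))
      expect_equal(
        sort(got$statistic),
        sort(exp_stats),
        tolerance = 1e-12
      )
    }
  })
})

test_that("mean and sum cluster statistics are consistent", {
  adj <- grid_adj(4)
  tm <- matrix(0, 4, 6)
  tm[1, 2:4] <- c(5, 6, 5)
  mean_cl <- form_clusters(tm, adj, cluster_config(4, 100, statistic = "mean_t"))
  sum_cl <- form_clusters(tm, adj, cluster_config(4, 100, statistic = "sum_t"))
  expect_equal(mean_cl$statistic, 16 / 3)
  expect_equal(sum_cl$statistic, 16)
})

test_that("raising the forming threshold only shrinks clusters", {
  adj <- grid_adj(8)
  withr::with_seed(3, tm <- matrix(rnorm(8 * 12, sd = 2.5), 8, 12))
  lo <- form_clusters(tm, adj, cluster_config(2, 100))
  hi <- form_clusters(tm, adj, cluster_config(3.5, 100))
  lo_keys <- lapply(lo$members, function(m) paste(m[, 1], m[, 2]))
  for (i in seq_len(nrow(hi))) {
    hi_key <- paste(hi$members[[i]][, 1], hi$members[[i]][, 2])
    contained <- any(vapply(lo_keys, function(k) all(hi_key %in% k), logical(1)))
    expect_true(contained)
  }
  expect_lte(sum(hi$n_points), sum(lo$n_points))
})

test_that("sensor relabeling leaves cluster statistics invariant", {
  adj <- grid_adj(6)
  withr::with_seed(4, tm <- matrix(rnorm(36, sd = 2), 6, 6))
  perm <- c(4, 1, 6, 2, 5, 3)
  cl1 <- form_clusters(tm, adj, cluster_config(2.5, 100))
  cl2 <- form_clusters(tm[perm, ], adj[perm, perm], cluster_config(2.5, 100))
  expect_equal(sort(cl1$statistic), sort(cl2$statistic), tolerance = 1e-12)
  expect_identical(sort(cl1$n_points), sort(cl2$n_points))
})

test_that("a uniform planted block is found by the sign-flip test at floor p", {
  n <- 12
  withr::with_seed(99, {
    arr <- array(rnorm(n * 5 * 20, sd = 1e-4), c(n, 5, 20))
  })
  # sensors 1-3 share a grid row, so the block is spatially contiguous
  arr[, 1:3, 6:15] <- arr[, 1:3, 6:15] + 1 # same sign for every subject
  cf <- as_contrast_field(arr, times_ms = seq(0, by = 4, length.out = 20))
  adj <- grid_adj(5)
  res <- signflip_contrast_test(cf, adj, cluster_config(4, 200, seed = 5))
  # the block is the dominant cluster, significant at the +1-corrected floor
  block <- res$clusters[1, ]
  expect_true(block$significant)
  expect_equal(block$monte_carlo_p, 1 / 201, tolerance = 1e-12)
  expect_identical(block$n_sensors, 3L)
  members <- block$members[[1]]
  expect_setequal(unique(members[, 1]), 1:3)
  expect_setequal(unique(members[, 2]), 6:15)
})

test_that("sign-flip p values are reproducible and need enough subjects", {
  cf <- make_null_contrast(10, 4, 12, seed = 6)
  adj <- grid_adj(4)
  cfg <- cluster_config(2, 150, seed = 7)
  a <- signflip_contrast_test(cf, adj, cfg)
  b <- signflip_contrast_test(cf, adj, cfg)
  expect_identical(a$clusters$monte_carlo_p, b$clusters$monte_carlo_p)
  tiny <- as_contrast_field(cf$data[1:5, , , drop = FALSE], times_ms = cf$times_ms)
  expect_error(signflip_contrast_test(tiny, adj, cfg), ">= 8 subjects")
})

test_that("sign-flip Monte Carlo p agrees with exhaustive enumeration", {
  n <- 10
  withr::with_seed(8, {
    arr <- array(rnorm(n * 4 * 5), c(n, 4, 5))
    arr[, 2, 2:4] <- arr[, 2, 2:4] + 1.2
  })
  cf <- as_contrast_field(arr, times_ms = seq(0, 16, by = 4))
  adj <- grid_adj(4)
  cfg <- cluster_config(2.5, 2000, seed = 9)
  res <- signflip_contrast_test(cf, adj, cfg)
  expect_gt(nrow(res$clusters), 0)
  # exact null: all 2^10 sign patterns, independent t and flood-fill oracle
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  null_max <- apply(signs, 1, function(sg) {
    flipped <- arr * sg # recycles over the subject dimension
    tm <- oracle_one_sample_t(flipped)
    cls <- oracle_clusters(tm, adj, 2.5)
    if (!length(cls)) return(0)
    max(vapply(cls, function(m) abs(mean(tm[m])), numeric(1)))
  })
  for (i in seq_len(nrow(res$clusters))) {
    exact_p <- mean(null_max >= abs(res$clusters$statistic[i]))
    expect_lt(abs(res$clusters$monte_carlo_p[i] - exact_p), 0.02)
  }
})

test_that("identity-only shuffles give p = 1 and unchanged statistics", {
  withr::with_seed(10, {
    covs <- data.frame(a = rnorm(12), b = rnorm(12))
    cf <- as_contrast_field(array(rnorm(12 * 4 * 8, sd = 1), c(12, 4, 8)),
      times_ms = 1:8
    )
  })
  cf$data[, 1, 1] <- cf$data[, 1, 1] + 3 * scale(covs$a)[, 1]
  design <- build_design_matrix(covs, c("a", "b"))
  adj <- grid_adj(4)
  res <- regressor_shuffle_glm_test(
    design, cf, "a", adj, cluster_config(2.8, 100),
    .permutations = list(1:12)
  )
  expect_gt(nrow(res$clusters), 0)
  expect_true(all(res$clusters$monte_carlo_p == 1))
  fit <- fit_ols(design, cf)
  expect_equal(res$t_map, matrix(fit$t_values["a", , ], 4, 8), tolerance = 1e-12)
  expect_error(
    regressor_shuffle_glm_test(design, cf, "zzz", adj, cluster_config(2.8, 100)),
    "unknown regressor"
  )
})

test_that("regressor shuffling preserves other covariates' effects (specificity)", {
  # covariate b carries a real effect; target a does not. The a-test should
  # stay null-calibrated across repeated simulated datasets.
  adj <- grid_adj(6)
  hits <- vapply(1:60, function(i) {
    withr::with_seed(1000 + i, {
      covs <- data.frame(a = rnorm(14), b = rnorm(14))
      arr <- array(rnorm(14 * 6 * 15), c(14, 6, 15))
      arr[, 1:2, 4:9] <- arr[, 1:2, 4:9] + 2 * scale(covs$b)[, 1]
    })
    cf <- as_contrast_field(arr, times_ms = seq_len(15))
    design <- build_design_matrix(covs, c("a", "b"))
    res <- regressor_shuffle_glm_test(design, cf, "a", adj,
      cluster_config(2.8, 150, seed = 2000 + i)
    )
    any(res$clusters$significant)
  }, logical(1))
  # alpha 0.05 with 60 draws: allow two binomial SEs above nominal
  expect_lte(mean(hits), 0.05 + 2 * sqrt(0.05 * 0.95 / 60))
})

test_that("cluster tables report onsets and extents in ms", {
  empty <- cluster_table(
    form_clusters(matrix(0, 3, 4), grid_adj(3), cluster_config(4, 100)),
    times_ms = 1:4
  )
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("statistic", "monte_carlo_p", "n_sensors", "onset_ms", "extent_ms")
    %in% names(empty)))
  # single-sensor run spanning samples 10-20 at 250 Hz: extent (20-10)*4 = 40 ms
  tm <- matrix(0, 3, 30)
  tm[2, 10:20] <- 5
  times <- seq(0, by = 4, length.out = 30)
  iso <- matrix(FALSE, 3, 3)
  tab <- cluster_table(form_clusters(tm, iso, cluster_config(4, 100)),
    times_ms = times, all = TRUE
  )
  expect_equal(tab$onset_ms, times[10])
  expect_equal(tab$extent_ms, 40)
  # single-point cluster: one sample step
  tm2 <- matrix(0, 3, 30)
  tm2[1, 7] <- 5
  tab2 <- cluster_table(form_clusters(tm2, iso, cluster_config(4, 100)),
    times_ms = times, all = TRUE
  )
  expect_equal(tab2$onset_ms, times[7])
  expect_equal(tab2$extent_ms, 4)
})
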