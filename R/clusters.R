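#' Configuration for cluster-based permutation inference
#'
#' @param cluster_forming_t Positive |t| threshold above which adjacent
#'   supra-threshold (sensor, timepoint) elements are merged into candidate
#'   clusters. The reference analysis uses 4 for the mismatch contrast test
#'   and 2.8 for the GLM regressor tests.
#' @param n_permutations Monte Carlo permutations for the null (>= 100;
#'   default 5000).
#' @param alpha Monte Carlo significance level (two-sided via the
#'   absolute-value convention; default 0.05, i.e. the 95th percentile of
#'   the max-statistic null).
#' @param statistic Cluster summary: `"mean_t"` (mean of member t values,
#'   the default) or `"sum_t"` (cluster mass).
#' @param seed Optional integer seed for the permutation draw.
#' @return A `cluster_config` list.
#' @export
cluster_config <- function(cluster_forming_t, n_permutations = 5000L,
                           alpha = 0.05, statistic = c("mean_t", "sum_t"),
                           seed = NULL) {
  if (cluster_forming_t <= 0) abort("'cluster_forming_t' must be positive")
  if (alpha <= 0 || alpha >= 1) abort("'alpha' must be in (0, 1)")
  if (n_permutations < 100L) abort("'n_permutations' must be >= 100")
  structure(
    list(
      cluster_forming_t = cluster_forming_t,
      n_permutations = as.integer(n_permutations),
      alpha = alpha, statistic = match.arg(statistic), seed = seed
    ),
    class = "cluster_config"
  )
}

#' Spatio-temporal neighbours of a (sensor, timepoint) element
#'
#' Two grid elements are neighbours when they share a timepoint and their
#' sensors are spatially adjacent, or share a sensor and sit at consecutive
#' timepoints.
#'
#' @param sensor,timepoint Indices of the element.
#' @param adjacency Symmetric logical sensor adjacency matrix.
#' @param n_timepoints Number of timepoints on the grid.
#' @return Tibble of neighbouring `sensor`, `timepoint` indices.
#' @export
spatiotemporal_neighbors <- function(sensor, timepoint, adjacency, n_timepoints) {
  stopifnot(sensor >= 1, sensor <= nrow(adjacency),
            timepoint >= 1, timepoint <= n_timepoints)
  spatial <- which(adjacency[sensor, ])
  temporal <- c(if (timepoint > 1) timepoint - 1L, if (timepoint < n_timepoints) timepoint + 1L)
  dplyr::bind_rows(
    tibble::tibble(sensor = spatial, timepoint = as.integer(timepoint)),
    tibble::tibble(sensor = as.integer(sensor), timepoint = as.integer(temporal))
  )
}

# Adjacency matrix -> list of neighbour index vectors per sensor.
adjacency_list <- function(adjacency) {
  lapply(seq_len(nrow(adjacency)), function(i) which(adjacency[i, ]))
}

# Connected components of the supra-threshold set (grid indices `supra`,
# member signs `sgn`) under the spatio-temporal adjacency. Returns a list of
# integer vectors indexing into `supra`. Iterative depth-first search; signs
# must match for membership (positive and negative excursions never merge).
label_components <- function(supra, sgn, n_sensors, n_times, adj_list) {
  m <- length(supra)
  if (m == 0L) return(list())
  rank <- integer(n_sensors * n_times)
  rank[supra] <- seq_len(m)
  comp <- integer(m)
  nc <- 0L
  for (i in seq_len(m)) {
    if (comp[i]) next
    nc <- nc + 1L
    comp[i] <- nc
    stack <- i
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      g <- supra[cur]
      s <- ((g - 1L) %% n_sensors) + 1L
      tt <- ((g - 1L) %/% n_sensors) + 1L
      nb_g <- c(
        if (tt > 1L) g - n_sensors,
        if (tt < n_times) g + n_sensors,
        adj_list[[s]] + (tt - 1L) * n_sensors
      )
      nb <- rank[nb_g]
      nb <- nb[nb > 0L]
      nb <- nb[comp[nb] == 0L & sgn[nb] == sgn[cur]]
      if (length(nb)) {
        comp[nb] <- nc
        stack <- c(stack, nb)
      }
    }
  }
  unname(split(seq_len(m), comp))
}

# Fast path for permutation nulls: the largest |cluster statistic| of a t
# map, or 0 when nothing is supra-threshold.
max_cluster_stat <- function(t_mat, adj_list, threshold, statistic) {
  supra <- which(abs(t_mat) > threshold)
  if (!length(supra)) return(0)
  vals <- t_mat[supra]
  comps <- label_components(supra, sign(vals), nrow(t_mat), ncol(t_mat), adj_list)
  stats <- vapply(comps, function(idx) {
    if (statistic == "mean_t") mean(vals[idx]) else sum(vals[idx])
  }, numeric(1))
  max(abs(stats))
}

#' Form spatio-temporal clusters from a t map
#'
#' Connected components of the supra-threshold set `{|t| >
#' cluster_forming_t}` under the sensor-adjacency x time grid, computed
#' separately for positive and negative excursions (two-tailed convention:
#' thresholding on |t| with the sign recorded). The cluster statistic is the
#' signed mean (or sum) of member t values. Output is ordered by
#' |statistic| descending, ties broken by earliest onset then lowest sensor
#' index.
#'
#' @param t_map `sensor x timepoint` matrix of finite t values.
#' @param adjacency Symmetric logical sensor adjacency matrix (or a
#'   `sensor_array`).
#' @param config A [cluster_config()] supplying threshold and statistic.
#' @return A `cluster_set` tibble: `cluster`, `statistic`, `sign`,
#'   `n_sensors`, `n_points`, `onset_idx`, `offset_idx`, and a `members`
#'   list-column of `(sensor_idx, time_idx)` matrices. Empty (zero rows)
#'   when nothing is supra-threshold.
#' @export
form_clusters <- function(t_map, adjacency, config) {
  if (inherits(adjacency, "sensor_array")) adjacency <- adjacency$adjacency
  if (any(!is.finite(t_map))) abort("'t_map' must be finite")
  S <- nrow(t_map)
  nT <- ncol(t_map)
  adj_list <- adjacency_list(adjacency)
  supra <- which(abs(t_map) > config$cluster_forming_t)
  empty <- tibble::tibble(
    cluster = integer(), statistic = numeric(), sign = character(),
    n_sensors = integer(), n_points = integer(),
    onset_idx = integer(), offset_idx = integer(), members = list()
  )
  if (!length(supra)) {
    return(structure(empty, class = c("cluster_set", class(empty)),
                     threshold = config$cluster_forming_t,
                     statistic = config$statistic, dims = c(S, nT)))
  }
  vals <- t_map[supra]
  comps <- label_components(supra, sign(vals), S, nT, adj_list)
  rows <- purrr::map_dfr(comps, function(idx) {
    g <- supra[idx]
    sens <- ((g - 1L) %% S) + 1L
    tim <- ((g - 1L) %/% S) + 1L
    stat <- if (config$statistic == "mean_t") mean(vals[idx]) else sum(vals[idx])
    tibble::tibble(
      statistic = stat,
      sign = if (stat >= 0) "+" else "-",
      n_sensors = length(unique(sens)),
      n_points = length(idx),
      onset_idx = min(tim),
      offset_idx = max(tim),
      min_sensor = min(sens),
      members = list(cbind(sensor_idx = sens, time_idx = tim))
    )
  })
  rows <- dplyr::arrange(rows, dplyr::desc(abs(.data$statistic)),
                         .data$onset_idx, .data$min_sensor)
  rows$min_sensor <- NULL
  rows <- dplyr::mutate(rows, cluster = dplyr::row_number(), .before = 1)
  structure(rows, class = c("cluster_set", class(empty)),
            threshold = config$cluster_forming_t,
            statistic = config$statistic, dims = c(S, nT))
}

# Attach Monte Carlo p values from a null vector of max statistics, with the
# +1 correction so p is never 0, and flag significance at alpha.
attach_p <- function(clusters, null_max, alpha) {
  B <- length(null_max)
  p <- vapply(clusters$statistic, function(s) (1 + sum(null_max >= abs(s))) / (1 + B),
              numeric(1))
  dplyr::mutate(clusters, monte_carlo_p = p, significant = p <= alpha)
}

new_cluster_test <- function(clusters, null_max, config, t_map, times_ms,
                             sensor_ids, engine, dof, extra = list()) {
  structure(
    c(list(
      clusters = clusters, null_max = null_max, config = config,
      t_map = t_map, times_ms = times_ms, sensor_ids = sensor_ids,
      engine = engine, dof = dof
    ), extra),
    class = "cluster_test"
  )
}

#' Sign-flip cluster permutation test on per-subject difference fields
#'
#' The nonparametric repeated-measures contrast test: the observed one-sample
#' t map (mean over subjects divided by its standard error, dof n - 1) is
#' clustered at the forming threshold; the null is built by randomly negating
#' each subject's whole difference field, recomputing the t map, reclustering
#' at the same threshold and recording the maximum |cluster statistic|
#' (0 when nothing survives). A cluster's Monte Carlo p is the proportion of
#' null maxima at least as large as its |statistic| (+1 corrected), so
#' comparing against alpha = 0.05 keeps clusters in the 95th percentile of
#' the max-statistic null — family-wise error is controlled.
#'
#' @param contrasts A `contrast_field` of per-subject difference fields
#'   (>= 8 subjects).
#' @param sensors A `sensor_array` (or adjacency matrix).
#' @param config A [cluster_config()] (reference threshold: t = 4).
#' @param .signs Optional `B x n_subjects` matrix of +/-1 flips overriding
#'   the random draw (used for exhaustive enumeration on small n).
#' @return A `cluster_test` with the observed clusters (`monte_carlo_p`,
#'   `significant` columns), the null maxima, the observed t map, and
#'   metadata. See [cluster_table()].
#' @export
signflip_contrast_test <- function(contrasts, sensors, config, .signs = NULL) {
  stopifnot(inherits(contrasts, "contrast_field"), inherits(config, "cluster_config"))
  adjacency <- if (inherits(sensors, "sensor_array")) sensors$adjacency else sensors
  d <- dim(contrasts$data)
  n <- d[1]
  if (n < 8L) {
    abort(sprintf("sign-flip permutation needs >= 8 subjects for resolution, got %d", n))
  }
  Y <- matrix(contrasts$data, nrow = n)
  ss <- colSums(Y^2) # invariant under sign flips
  one_sample_t <- function(m) {
    sd_ <- sqrt(pmax(ss / (n - 1) - n * m^2 / (n - 1), 0))
    se <- sd_ / sqrt(n)
    tt <- m / se
    tt[se == 0] <- 0
    tt
  }
  t_obs <- matrix(one_sample_t(colMeans(Y)), d[2], d[3])
  clusters <- form_clusters(t_obs, adjacency, config)
  adj_list <- adjacency_list(adjacency)
  null_max <- with_seed_(config$seed, {
    signs <- if (is.null(.signs)) {
      matrix(sample(c(-1, 1), config$n_permutations * n, replace = TRUE),
             ncol = n)
    } else {
      .signs
    }
    apply(signs, 1, function(sg) {
      tb <- matrix(one_sample_t(as.numeric(sg %*% Y) / n), d[2], d[3])
      max_cluster_stat(tb, adj_list, config$cluster_forming_t, config$statistic)
    })
  })
  clusters <- attach_p(clusters, null_max, config$alpha)
  new_cluster_test(clusters, null_max, config, t_obs, contrasts$times_ms,
                   contrasts$sensor_ids, "signflip", dof = n - 1L)
}

#' Regressor-shuffle cluster permutation test for one GLM covariate
#'
#' Observed clusters come from the target regressor's t map of the full OLS
#' fit. For each permutation only the target column's rows are shuffled
#' (covariates held fixed, so the regressor no longer matches the subjects'
#' data), the full model is refit at every (sensor, timepoint), the target's
#' t map is reclustered at the same threshold, and the maximum |cluster
#' statistic| enters the max-statistic null. Monte Carlo p and significance
#' as in [signflip_contrast_test()]. Run once per non-intercept regressor to
#' reproduce the per-regressor family of tests.
#'
#' @param design A [build_design_matrix()] result.
#' @param contrasts A `contrast_field` aligned with the design.
#' @param target_regressor Name of the regressor under test (not the
#'   intercept by default).
#' @param sensors A `sensor_array` (or adjacency matrix).
#' @param config A [cluster_config()] (reference threshold: t = 2.8).
#' @param .permutations Optional list of row-index vectors overriding the
#'   random shuffles (e.g. the identity permutation, for which every p is 1).
#' @return A `cluster_test` (engine `"regressor_shuffle"`).
#' @export
regressor_shuffle_glm_test <- function(design, contrasts, target_regressor,
                                       sensors, config, .permutations = NULL) {
  stopifnot(inherits(design, "design_matrix"), inherits(config, "cluster_config"))
  adjacency <- if (inherits(sensors, "sensor_array")) sensors$adjacency else sensors
  if (!target_regressor %in% design$regressor_names) {
    abort(sprintf(
      "unknown regressor '%s' (design has: %s)",
      target_regressor, paste(design$regressor_names, collapse = ", ")
    ))
  }
  fit <- fit_ols(design, contrasts)
  j <- match(target_regressor, design$regressor_names)
  d <- dim(contrasts$data)
  t_obs <- matrix(fit$t_values[j, , ], d[2], d[3])
  clusters <- form_clusters(t_obs, adjacency, config)
  adj_list <- adjacency_list(adjacency)

  X <- design$X
  n <- nrow(X)
  Y <- matrix(contrasts$data, nrow = n)
  target_t_map <- function(Xp) {
    qrX <- qr(Xp)
    beta <- qr.coef(qrX, Y)
    sigma2 <- colSums((Y - Xp %*% beta)^2) / fit$dof
    dj <- diag(solve(crossprod(Xp)))[j]
    matrix(beta[j, ] / sqrt(sigma2 * dj), d[2], d[3])
  }
  null_max <- with_seed_(config$seed, {
    perms <- if (is.null(.permutations)) {
      replicate(config$n_permutations, sample.int(n), simplify = FALSE)
    } else {
      .permutations
    }
    vapply(perms, function(pm) {
      Xp <- X
      Xp[, j] <- X[pm, j]
      max_cluster_stat(target_t_map(Xp), adj_list,
                       config$cluster_forming_t, config$statistic)
    }, numeric(1))
  })
  clusters <- attach_p(clusters, null_max, config$alpha)
  new_cluster_test(clusters, null_max, config, t_obs, contrasts$times_ms,
                   contrasts$sensor_ids, "regressor_shuffle", dof = fit$dof,
                   extra = list(target_regressor = target_regressor))
}

#' Report clusters the way evoked-cluster tables are published
#'
#' One row per cluster with the signed statistic, Monte Carlo p, number of
#' distinct sensors, onset time and temporal extent. Onset and extent are
#' descriptive estimates only — the permutation scheme tests the cluster
#' statistic, not its location. Extent is `(offset - onset)` sample steps in
#' ms, with a floor of one sample step for single-sample clusters.
#'
#' @param test A `cluster_test` (or a `cluster_set` plus `times_ms`).
#' @param times_ms Time axis; taken from the test when omitted.
#' @param all Report all clusters (`TRUE`) or significant ones only (the
#'   default, mirroring published tables).
#' @return Tibble: `cluster`, `sign`, `statistic`, `monte_carlo_p`,
#'   `n_sensors`, `onset_ms`, `extent_ms`, `significant`.
#' @export
cluster_table <- function(test, times_ms = NULL, all = FALSE) {
  if (inherits(test, "cluster_test")) {
    clusters <- test$clusters
    if (is.null(times_ms)) times_ms <- test$times_ms
  } else {
    clusters <- test
    if (is.null(times_ms)) abort("'times_ms' is required when passing a bare cluster set")
  }
  if (!"monte_carlo_p" %in% names(clusters)) {
    clusters$monte_carlo_p <- NA_real_
    clusters$significant <- NA
  }
  dt <- if (length(times_ms) > 1) times_ms[2] - times_ms[1] else NA_real_
  out <- clusters |>
    dplyr::mutate(
      onset_ms = times_ms[.data$onset_idx],
      extent_ms = pmax((.data$offset_idx - .data$onset_idx) * dt, dt)
    ) |>
    dplyr::select(
      "cluster", "sign", "statistic", "monte_carlo_p", "n_sensors",
      "onset_ms", "extent_ms", "significant"
    )
  if (!all) out <- dplyr::filter(out, .data$significant %in% TRUE)
  out
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf(
    "<cluster_test %s> threshold |t| > %g, %d permutations, alpha %g\n",
    x$engine, x$config$cluster_forming_t, length(x$null_max), x$config$alpha
  ))
  cat(sprintf(
    "%d cluster(s), %d significant\n",
    nrow(x$clusters), sum(x$clusters$significant)
  ))
  if (nrow(x$clusters)) print(cluster_table(x, all = TRUE), n = 10)
  invisible(x)
}

#' @describeIn cluster_table Full cluster table (all clusters) as a tibble.
#' @param x A `cluster_test`.
#' @param ... Unused.
#' @method tidy cluster_test
#' @export
tidy.cluster_test <- function(x, ...) cluster_table(x, all = TRUE)

#' @describeIn cluster_table One-row test summary.
#' @method glance cluster_test
#' @export
glance.cluster_test <- function(x, ...) {
  tibble::tibble(
    engine = x$engine,
    target = if (!is.null(x$target_regressor)) x$target_regressor else NA_character_,
    threshold = x$config$cluster_forming_t,
    n_permutations = length(x$null_max),
    n_clusters = nrow(x$clusters),
    n_significant = sum(x$clusters$significant),
    min_p = if (nrow(x$clusters)) min(x$clusters$monte_carlo_p) else NA_real_,
    dof = x$dof
  )
}

#' @method autoplot cluster_test
#' @export
autoplot.cluster_test <- function(object, ...) {
  S <- nrow(object$t_map)
  df <- tibble::tibble(
    sensor = rep(seq_len(S), times = ncol(object$t_map)),
    time_ms = rep(object$times_ms, each = S),
    t = as.vector(object$t_map)
  )
  sig <- dplyr::filter(object$clusters, .data$significant)
  memb <- if (nrow(sig)) {
    purrr::map_dfr(sig$members, function(m) {
      tibble::tibble(sensor = m[, 1], time_ms = object$times_ms[m[, 2]])
    })
  } else {
    tibble::tibble(sensor = integer(), time_ms = numeric())
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$sensor, fill = .data$t)) +
    ggplot2::geom_raster() +
    ggplot2::geom_point(data = memb, ggplot2::aes(.data$time_ms, .data$sensor),
                        inherit.aes = FALSE, shape = 0, size = 1, colour = "black") +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(
      title = sprintf("t map with significant clusters (%s)", object$engine),
      x = "time (ms)", y = "sensor index"
    ) +
    ggplot2::theme_minimal()
}
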