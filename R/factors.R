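#' Z-score every numeric column of a table
#'
#' Uses the population standard deviation (divide by n), the convention fixed
#' package-wide for regressor standardization; output columns have mean 0 and
#' population SD 1 to within 1e-10.
#'
#' @param data A data frame of numeric columns.
#' @return A tibble of the standardized columns.
#' @examples
#' zscore_table(data.frame(x = c(1, 2, 3)))  # -1.2247, 0, 1.2247
#' @export
zscore_table <- function(data) {
  out <- purrr::imap(as.list(data), function(col, nm) zscore_vec(as.numeric(col), nm))
  tibble::as_tibble(out)
}

#' Principal component analysis of a standardized battery
#'
#' Eigendecomposition of the correlation matrix: eigenvalues in descending
#' order, loadings = eigenvectors scaled by the square root of their
#' eigenvalue (so squared loadings per component sum to the component's
#' eigenvalue, and eigenvalues sum to the number of variables).
#'
#' @param data Standardized table (columns mean 0, SD 1), one row per subject.
#' @return A `battery_pca` list: `eigenvalues`, `loadings` (variable x
#'   component), `variance_fraction`, `n`.
#' @export
battery_pca <- function(data) {
  X <- as.matrix(data)
  if (any(!is.finite(X))) abort("input contains non-finite values")
  if (nrow(X) <= ncol(X)) {
    warn(sprintf(
      "only %d subjects for %d variables; components beyond n - 1 are degenerate",
      nrow(X), ncol(X)
    ))
  }
  ev <- eigen(stats::cor(X), symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  loadings <- ev$vectors %*% diag(sqrt(lam), length(lam))
  dimnames(loadings) <- list(colnames(X), paste0("PC", seq_along(lam)))
  structure(
    list(
      eigenvalues = lam, loadings = loadings,
      variance_fraction = lam / length(lam), n = nrow(X)
    ),
    class = "battery_pca"
  )
}

#' Varimax criterion of a loading matrix
#'
#' Sum over factors of the variance of squared loadings; the quantity an
#' orthogonal varimax rotation maximizes (raw criterion, no row
#' normalization).
#'
#' @param loadings Variable x factor matrix.
#' @return Scalar criterion value.
#' @export
varimax_criterion <- function(loadings) {
  L2 <- loadings^2
  sum(colMeans(L2^2) - colMeans(L2)^2)
}

#' Varimax rotation of component loadings
#'
#' Orthogonal rotation toward simple structure. With Kaiser row
#' normalization (the default) rows are scaled to unit communality before
#' rotating and scaled back after; communalities are invariant either way.
#' A single-factor input returns the identity rotation.
#'
#' @param loadings Variable x factor loading matrix (>= 1 factor).
#' @param normalize Kaiser row normalization.
#' @param eps Convergence tolerance on the criterion gain.
#' @return List with rotated `loadings` and the orthogonal `rotmat`.
#' @export
rotate_varimax <- function(loadings, normalize = TRUE, eps = 1e-8) {
  loadings <- as.matrix(loadings)
  k <- ncol(loadings)
  if (k < 2L) {
    return(list(loadings = loadings, rotmat = diag(1)))
  }
  # The planar-rotation iteration can stall on a zero-gradient saddle when
  # the unrotated loadings are exactly symmetric (e.g. tied eigenvalues of a
  # noiseless battery). Restart from a few fixed orthogonal rotations and
  # keep the solution with the largest criterion; deterministic by design.
  starts <- list(diag(k))
  for (angle in c(pi / 7, pi / 3)) {
    G <- diag(k)
    for (i in seq_len(k - 1)) {
      R <- diag(k)
      R[i, i] <- R[i + 1, i + 1] <- cos(angle)
      R[i, i + 1] <- sin(angle)
      R[i + 1, i] <- -sin(angle)
      G <- G %*% R
    }
    starts <- c(starts, list(G))
  }
  best <- NULL
  for (Q0 in starts) {
    v <- stats::varimax(loadings %*% Q0, normalize = normalize, eps = eps)
    rotmat <- Q0 %*% v$rotmat
    cand <- loadings %*% rotmat
    crit <- varimax_criterion(cand)
    if (is.null(best) || crit > best$crit + 1e-12) {
      best <- list(loadings = cand, rotmat = rotmat, crit = crit)
    }
  }
  L <- best$loadings
  dimnames(L) <- dimnames(loadings)
  list(loadings = L, rotmat = best$rotmat)
}

#' Horn's parallel analysis for component retention
#'
#' Retains the leading components whose observed correlation-matrix
#' eigenvalues exceed the given percentile of eigenvalues from `n_iter`
#' same-shape standard-normal datasets; stops at the first component that
#' fails.
#'
#' @param data Standardized table, one row per subject.
#' @param n_iter Number of null datasets (>= 100).
#' @param percentile Null percentile to beat (default 95).
#' @param seed Optional integer seed.
#' @return A `parallel_analysis` list: `n_factors`, `observed`, `threshold`.
#' @export
parallel_analysis <- function(data, n_iter = 200L, percentile = 95, seed = NULL) {
  if (n_iter < 100L) abort("'n_iter' must be >= 100 for a stable percentile")
  X <- as.matrix(data)
  n <- nrow(X)
  p <- ncol(X)
  obs <- eigen(stats::cor(X), symmetric = TRUE, only.values = TRUE)$values
  with_seed_(seed, {
    null_eig <- vapply(seq_len(n_iter), function(i) {
      eigen(stats::cor(matrix(rnorm(n * p), n, p)),
        symmetric = TRUE, only.values = TRUE
      )$values
    }, numeric(p))
    thr <- apply(null_eig, 1, quantile, probs = percentile / 100)
    keep <- obs > thr
    k <- if (keep[1]) which.min(c(keep, FALSE)) - 1L else 0L
    structure(
      list(n_factors = as.integer(k), observed = obs, threshold = thr,
           percentile = percentile, n_iter = n_iter),
      class = "parallel_analysis"
    )
  })
}

#' @export
print.parallel_analysis <- function(x, ...) {
  cat(sprintf(
    "<parallel_analysis> retain %d component(s) (observed eigenvalues vs %gth null percentile)\n",
    x$n_factors, x$percentile
  ))
  invisible(x)
}

#' Regression (Thurstone) factor scores
#'
#' `scores = Z R^-1 L` for standardized data `Z`, its correlation matrix `R`
#' and rotated loadings `L`.
#'
#' @param data Standardized table used to fit the loadings.
#' @param loadings Variable x factor rotated loading matrix.
#' @return `subject x factor` score matrix.
#' @export
factor_scores <- function(data, loadings) {
  Z <- as.matrix(data)
  if (!identical(colnames(Z), rownames(loadings)) &&
      !is.null(rownames(loadings))) {
    loadings <- loadings[colnames(Z), , drop = FALSE]
  }
  if (qr(loadings)$rank < ncol(loadings)) {
    abort("collinear loading columns: factor scores are not identified")
  }
  R <- stats::cor(Z)
  # noiseless low-rank batteries make R singular; the Moore-Penrose inverse
  # gives the minimum-norm regression weights in that case
  W <- tryCatch(solve(R, loadings), error = function(e) MASS::ginv(R) %*% loadings)
  S <- Z %*% W
  colnames(S) <- colnames(loadings)
  S
}

#' Fit a rotated principal-component factor model to a behavioral battery
#'
#' The battery-reduction pipeline: drop near-constant (ceiling-effect)
#' columns, z-score, extract components of the correlation matrix, choose
#' how many to keep (parallel analysis by default, or a fixed `n_factors`),
#' varimax-rotate, and compute regression factor scores.
#'
#' @param data Data frame of raw battery columns (one row per subject).
#' @param n_factors Number of factors to retain; `NULL` (default) uses
#'   parallel analysis.
#' @param normalize Kaiser row normalization for the rotation.
#' @param ceiling_prop Columns whose modal value covers at least this
#'   proportion of subjects are dropped with a warning (ceiling effects give
#'   them almost no variance).
#' @param seed Seed for the parallel-analysis null.
#' @return A `factor_model`: rotated `loadings`, `rotmat`, `scores`,
#'   `eigenvalues`, per-factor and total `explained_variance_fraction`,
#'   `n_factors`, `dropped` columns.
#' @examples
#' cohort <- simulate_cohort(200, seed = 1)
#' fm <- fit_factor_model(cohort[battery_columns(cohort)], seed = 2)
#' glance(fm)
#' @export
fit_factor_model <- function(data, n_factors = NULL, normalize = TRUE,
                             ceiling_prop = 0.95, seed = NULL) {
  data <- tibble::as_tibble(data)
  modal_prop <- vapply(data, function(col) max(table(col)) / length(col), numeric(1))
  dropped <- names(data)[modal_prop >= ceiling_prop]
  if (length(dropped)) {
    warn(paste0(
      "dropping near-constant column(s) (>= ", ceiling_prop * 100,
      "% identical values, ceiling effect): ", paste(dropped, collapse = ", ")
    ))
    data <- data[setdiff(names(data), dropped)]
  }
  Z <- zscore_table(data)
  pca <- battery_pca(Z)
  if (is.null(n_factors)) {
    n_factors <- parallel_analysis(Z, seed = seed)$n_factors
    if (n_factors < 1L) {
      warn("parallel analysis retained no components; keeping 1")
      n_factors <- 1L
    }
  }
  L <- pca$loadings[, seq_len(n_factors), drop = FALSE]
  rot <- rotate_varimax(L, normalize = normalize)
  colnames(rot$loadings) <- paste0("factor", seq_len(n_factors))
  scores <- factor_scores(Z, rot$loadings)
  per_factor <- colSums(rot$loadings^2) / ncol(Z)
  structure(
    list(
      loadings = rot$loadings, rotmat = rot$rotmat, scores = scores,
      eigenvalues = pca$eigenvalues,
      explained_variance_fraction = per_factor,
      total_variance_fraction = sum(per_factor),
      n_factors = n_factors, dropped = dropped, variables = rownames(rot$loadings)
    ),
    class = "factor_model"
  )
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf(
    "<factor_model> %d factor(s), %.1f%% of total variance\n",
    x$n_factors, 100 * x$total_variance_fraction
  ))
  print(round(x$loadings, 2))
  invisible(x)
}

#' @describeIn fit_factor_model Long tibble of rotated loadings
#'   (variable, factor, loading).
#' @param x A `factor_model`.
#' @param ... Unused.
#' @method tidy factor_model
#' @export
tidy.factor_model <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "variable") |>
    tidyr::pivot_longer(-"variable", names_to = "factor", values_to = "loading")
}

#' @describeIn fit_factor_model One-row summary (factors retained, variance
#'   explained, subjects).
#' @method glance factor_model
#' @export
glance.factor_model <- function(x, ...) {
  tibble::tibble(
    n_factors = x$n_factors,
    total_variance_fraction = x$total_variance_fraction,
    n_variables = nrow(x$loadings),
    n_subjects = nrow(x$scores),
    n_dropped = length(x$dropped)
  )
}

#' @method autoplot factor_model
#' @export
autoplot.factor_model <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$factor, .data$variable, fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$loading)), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(title = "Varimax-rotated loadings", x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' OECD-modified household equivalence scale
#'
#' Couple-normalized weights as used in UK households-below-average-income
#' statistics: 0.67 for the first adult, 0.33 for each additional adult or
#' child aged 14+, 0.20 for each child under 14 (a childless couple has
#' divisor 1).
#'
#' @param first_adult,additional_adult_or_child14plus,child_under14 Weights.
#' @return An `equivalence_scale` list.
#' @export
oecd_scale <- function(first_adult = 0.67,
                       additional_adult_or_child14plus = 0.33,
                       child_under14 = 0.20) {
  if (any(c(first_adult, additional_adult_or_child14plus, child_under14) <= 0)) {
    abort("equivalence-scale weights must be positive")
  }
  if (first_adult < max(additional_adult_or_child14plus, child_under14)) {
    abort("'first_adult' must be the largest weight")
  }
  structure(
    list(
      first_adult = first_adult,
      additional_adult_or_child14plus = additional_adult_or_child14plus,
      child_under14 = child_under14
    ),
    class = "equivalence_scale"
  )
}

#' Equivalized household income
#'
#' Net household income divided by the composition-dependent OECD weight so
#' living standards are comparable across household sizes:
#' `income / (first_adult + additional * (n_adults - 1 + n_children_14plus)
#' + child_under14 * n_children_under14)`.
#'
#' @param income_raw Net household income (currency/year), positive.
#' @param n_adults Number of adults (>= 1).
#' @param child_ages List of per-household child-age vectors (or a single
#'   numeric vector for one household).
#' @param scale An [oecd_scale()].
#' @return Numeric equivalized income, one per household.
#' @examples
#' equivalize_income(30000, 2, list(integer()))        # couple: unchanged
#' equivalize_income(30000, 1, list(c(5, 8)))          # divisor 1.07
#' @export
equivalize_income <- function(income_raw, n_adults, child_ages, scale = oecd_scale()) {
  if (!is.list(child_ages)) child_ages <- list(child_ages)
  if (any(income_raw <= 0)) abort("'income_raw' must be positive")
  if (any(n_adults < 1)) abort("households must contain at least one adult")
  n14plus <- vapply(child_ages, function(a) sum(a >= 14), numeric(1))
  nunder <- vapply(child_ages, function(a) sum(a < 14), numeric(1))
  divisor <- scale$first_adult +
    scale$additional_adult_or_child14plus * (n_adults - 1 + n14plus) +
    scale$child_under14 * nunder
  income_raw / divisor
}

#' Relative poverty classification
#'
#' TRUE when equivalized income is at or below 60% of the reference median
#' (inclusive: "60% of the median income or less"). The default reference is
#' the 2017/18 UK median equivalized household income, GBP 31,876.
#'
#' @param equivalized_income Positive equivalized income.
#' @param reference_median Positive reference median income.
#' @return Logical vector.
#' @export
poverty_flag <- function(equivalized_income, reference_median = 31876) {
  if (any(equivalized_income <= 0) || any(reference_median <= 0)) {
    abort("incomes must be positive")
  }
  equivalized_income <= 0.6 * reference_median
}
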