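# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: naive loops, pairwise scans and label propagation
# instead of the vectorized / stack-based implementations under test.

# Flood-fill cluster oracle: pairwise adjacency by definition, then label
# propagation to a fixpoint. Returns a list of (sensor, time) member
# matrices, unordered.
oracle_clusters <- function(t_map, adjacency, threshold) {
  pts <- which(abs(t_map) > threshold, arr.ind = TRUE)
  n <- nrow(pts)
  if (n == 0) return(list())
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j || lab[i] == lab[j]) next
        same_sign <- sign(t_map[pts[i, 1], pts[i, 2]]) ==
          sign(t_map[pts[j, 1], pts[j, 2]])
        neighbours <-
          (pts[i, 2] == pts[j, 2] && adjacency[pts[i, 1], pts[j, 1]]) ||
          (pts[i, 1] == pts[j, 1] && abs(pts[i, 2] - pts[j, 2]) == 1)
        if (same_sign && neighbours) {
          l <- min(lab[i], lab[j])
          lab[lab == lab[i] | lab == lab[j]] <- l
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lapply(split(seq_len(n), lab), function(g) {
    unname(pts[g, , drop = FALSE])
  })
}

# Canonical string form of a member set, for exact membership comparison.
member_key <- function(members) {
  paste(sort(paste(members[, 1], members[, 2], sep = "_")), collapse = ";")
}

# One-sample t map computed the slow way (per-point loop).
oracle_one_sample_t <- function(data3d) {
  d <- dim(data3d)
  out <- matrix(0, d[2], d[3])
  for (s in seq_len(d[2])) {
    for (k in seq_len(d[3])) {
      y <- data3d[, s, k]
      out[s, k] <- mean(y) / (sd(y) / sqrt(length(y)))
    }
  }
  out
}

# Per-point OLS by explicit normal equations (scalar loop oracle).
oracle_ols_point <- function(X, y) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% beta
  dof <- nrow(X) - ncol(X)
  sigma2 <- sum(resid^2) / dof
  se <- unname(sqrt(sigma2 * diag(solve(XtX))))
  list(beta = as.numeric(beta), se = se, t = as.numeric(beta) / se)
}

# Tucker congruence between two loading vectors.
tucker_congruence <- function(a, b) {
  abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
}

# Best column match of recovered loadings against planted loadings:
# greedy assignment on |congruence|, returns the matched congruences.
match_congruence <- function(recovered, planted) {
  k <- ncol(planted)
  cong <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      cong[i, j] <- tucker_congruence(recovered[, i], planted[, j])
    }
  }
  out <- numeric(k)
  for (step in seq_len(k)) {
    idx <- which(cong == max(cong), arr.ind = TRUE)[1, ]
    out[step] <- cong[idx[1], idx[2]]
    cong[idx[1], ] <- -1
    cong[, idx[2]] <- -1
  }
  out
}

# Characteristic-polynomial eigenvalue oracle, independent of LAPACK's
# symmetric eigensolver: det(M - lambda I) is sampled at p + 1 points,
# interpolated to polynomial coefficients, and root-found with polyroot().
oracle_eigenvalues <- function(M) {
  p <- nrow(M)
  xs <- seq(-2 * p, 2 * p, length.out = p + 1)
  ys <- vapply(xs, function(l) det(M - l * diag(p)), numeric(1))
  poly_coef <- solve(outer(xs, 0:p, `^`), ys) # coefficients a_0..a_p
  sort(Re(polyroot(poly_coef)), decreasing = TRUE)
}

# Raw varimax criterion (variance of squared loadings per factor).
oracle_varimax_criterion <- function(L) {
  L2 <- L^2
  sum(apply(L2, 2, function(col) mean(col^2) - mean(col)^2))
}

# Small helper: a quick simulated dataset for engine tests.
make_null_contrast <- function(n_subjects, n_sensors, n_times, seed) {
  withr::with_seed(seed, {
    as_contrast_field(
      array(rnorm(n_subjects * n_sensors * n_times), c(n_subjects, n_sensors, n_times)),
      times_ms = seq(0, by = 4, length.out = n_times)
    )
  })
}
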