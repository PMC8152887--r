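# Shared internal helpers.

# Population-SD z-score (divide by n, not n - 1). The convention matters for
# exact example values only; it is fixed package-wide and documented in the
# methods vignette.
zscore_vec <- function(x, name = "x") {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (!is.finite(s) || s == 0) {
    abort(sprintf("column '%s' has zero variance and cannot be z-scored", name))
  }
  (x - m) / s
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Evaluate `code` under a temporary RNG seed when one is supplied; leave the
# global RNG stream untouched by the call either way.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min) {
    abort(sprintf("'%s' must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

# Breadth-first connectivity check on a logical adjacency matrix.
graph_connected <- function(adj) {
  n <- nrow(adj)
  if (n == 0L) return(TRUE)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    nb <- which(adj[v, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}
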