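#' Build a 2D sensor array with a spatial adjacency graph
#'
#' Stands in for the helmet-plane layout of an MEG magnetometer array (the
#' reference system has 102 magnetometers). Positions live in an arbitrary
#' length unit on the 2D helmet plane; adjacency defines which sensors count
#' as spatial neighbours for cluster formation.
#'
#' @param n_sensors Number of sensors (>= 2).
#' @param layout `"grid"` (near-square lattice) or `"rings"` (concentric
#'   rings around a central sensor, helmet-like).
#' @param neighbor_rule `"distance"` (neighbours within `threshold`) or
#'   `"knn"` (symmetrized k-nearest neighbours).
#' @param spacing Lattice / ring spacing in layout units.
#' @param threshold Distance cutoff for the distance rule. The default,
#'   `1.01 * spacing`, gives the 4-neighbourhood on a grid.
#' @param k Number of neighbours for the knn rule.
#'
#' @return A `sensor_array`: list with `sensors` (tibble of `sensor`, `x`,
#'   `y`) and `adjacency` (symmetric, irreflexive logical matrix with sensor
#'   ids as dimnames).
#' @examples
#' arr <- build_sensor_array(102, layout = "rings", neighbor_rule = "knn", k = 4)
#' nrow(arr$sensors)
#' @export
build_sensor_array <- function(n_sensors,
                               layout = c("grid", "rings"),
                               neighbor_rule = c("distance", "knn"),
                               spacing = 1,
                               threshold = 1.01 * spacing,
                               k = 4L) {
  n_sensors <- stopifnot_scalar_count(n_sensors, "n_sensors", min = 2L)
  layout <- match.arg(layout)
  neighbor_rule <- match.arg(neighbor_rule)

  pos <- switch(layout,
    grid = {
      ncol_ <- ceiling(sqrt(n_sensors))
      idx <- seq_len(n_sensors) - 1L
      cbind(x = (idx %% ncol_) * spacing, y = (idx %/% ncol_) * spacing)
    },
    rings = {
      # centre sensor, then rings of radius r*spacing holding 6r sensors
      # (hexagonal packing density), trimmed to n_sensors.
      xs <- 0; ys <- 0; r <- 1L
      while (length(xs) < n_sensors) {
        m <- 6L * r
        th <- 2 * pi * (seq_len(m) - 1L) / m + (r %% 2L) * pi / m
        xs <- c(xs, r * spacing * cos(th))
        ys <- c(ys, r * spacing * sin(th))
        r <- r + 1L
      }
      cbind(x = xs[seq_len(n_sensors)], y = ys[seq_len(n_sensors)])
    }
  )
  ids <- sprintf("S%03d", seq_len(n_sensors))
  d <- as.matrix(stats::dist(pos))
  adj <- switch(neighbor_rule,
    distance = d <= threshold & d > 0,
    knn = {
      a <- matrix(FALSE, n_sensors, n_sensors)
      for (i in seq_len(n_sensors)) {
        nb <- order(d[i, ])[2:(min(k, n_sensors - 1L) + 1L)]
        a[i, nb] <- TRUE
      }
      a | t(a)
    }
  )
  diag(adj) <- FALSE
  dimnames(adj) <- list(ids, ids)

  structure(
    list(
      sensors = tibble::tibble(sensor = ids, x = pos[, "x"], y = pos[, "y"]),
      adjacency = adj,
      layout = layout, neighbor_rule = neighbor_rule, spacing = spacing
    ),
    class = "sensor_array"
  )
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf(
    "<sensor_array> %d sensors, %s layout, %s adjacency (%d edges, %sconnected)\n",
    nrow(x$sensors), x$layout, x$neighbor_rule, sum(x$adjacency) / 2,
    if (graph_connected(x$adjacency)) "" else "NOT "
  ))
  invisible(x)
}

#' @describeIn build_sensor_array Tidy sensor table with per-sensor degree.
#' @param x A `sensor_array`.
#' @param ... Unused.
#' @method tidy sensor_array
#' @export
tidy.sensor_array <- function(x, ...) {
  deg <- rowSums(x$adjacency) # computed outside mutate: 'x' is also a column
  dplyr::mutate(x$sensors, degree = deg)
}

#' @method autoplot sensor_array
#' @export
autoplot.sensor_array <- function(object, ...) {
  edges <- which(object$adjacency & upper.tri(object$adjacency), arr.ind = TRUE)
  seg <- tibble::tibble(
    x = object$sensors$x[edges[, 1]], y = object$sensors$y[edges[, 1]],
    xend = object$sensors$x[edges[, 2]], yend = object$sensors$y[edges[, 2]]
  )
  ggplot2::ggplot(object$sensors, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      colour = "grey70"
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Sensor array (helmet plane)", x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
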