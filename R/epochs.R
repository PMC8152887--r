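#' Construct a labeled epochs container
#'
#' Holds per-trial sensor-by-time field segments time-locked to stimulus
#' onset (default epoch -200 to +1000 ms), with a condition label per trial.
#'
#' @param data Numeric `trial x sensor x time` array.
#' @param labels Condition label per trial.
#' @param times_ms Strictly increasing epoch time axis in ms.
#' @param baseline_window_ms Pre-stimulus interval used as the default
#'   baseline.
#' @return An `epochs_set`.
#' @export
epochs_set <- function(data, labels, times_ms, baseline_window_ms = c(-200, 0)) {
  stopifnot(length(dim(data)) == 3L)
  if (length(labels) != dim(data)[1]) abort("length(labels) must equal the trial count")
  if (length(times_ms) != dim(data)[3]) abort("length(times_ms) must equal the time dimension")
  if (any(diff(times_ms) <= 0)) abort("'times_ms' must be strictly increasing")
  structure(
    list(
      data = data, labels = as.character(labels),
      times_ms = as.numeric(times_ms), baseline_window_ms = baseline_window_ms
    ),
    class = "epochs_set"
  )
}

#' @export
print.epochs_set <- function(x, ...) {
  cat(sprintf(
    "<epochs_set> %d trials x %d sensors x %d timepoints (%g-%g ms)\n",
    dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], min(x$times_ms), max(x$times_ms)
  ))
  print(table(x$labels))
  invisible(x)
}

#' Simulate trial-level epochs for one subject
#'
#' Each trial is the deterministic condition signal from the forward model
#' plus independent trial noise at the spec's full `noise_sd`. Intended for
#' small sessions; cohort-scale simulation goes through
#' [simulate_evoked_dataset()], which emits trial-averaged evoked fields
#' directly.
#'
#' @param labels Trial condition labels (e.g. `sequence$label` from
#'   [simulate_trial_sequence()]).
#' @param sensors A `sensor_array`.
#' @param spec An [effect_spec()].
#' @param covariate_z Named numeric vector of the subject's z-scored
#'   covariates (defaults to all zero, i.e. a cohort-average subject).
#' @inheritParams simulate_evoked_dataset
#' @return An `epochs_set`.
#' @export
simulate_epochs <- function(labels, sensors, spec, covariate_z = numeric(),
                            epoch_window = c(-200, 1000), sfreq = 250, seed = NULL) {
  labels <- as.character(labels)
  times <- seq(epoch_window[1], epoch_window[2], by = 1000 / sfreq)
  conds <- unique(labels)
  signals <- lapply(conds, condition_signal,
    spec = spec, sensors = sensors, times_ms = times, covariate_z = covariate_z
  )
  names(signals) <- conds
  n_sens <- nrow(sensors$sensors)
  with_seed_(seed, {
    data <- array(0, c(length(labels), n_sens, length(times)))
    for (i in seq_along(labels)) {
      data[i, , ] <- signals[[labels[i]]] +
        smoothed_noise(n_sens, length(times), spec$noise_sd, sensors$adjacency,
                       spec$spatial_noise_smoothing, spec$temporal_noise_smoothing)
    }
    epochs_set(data, labels, times)
  })
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and sensor, the mean field over the baseline window
#' (default the epochs' pre-stimulus interval), so post-stimulus deflections
#' are measured against the pre-stimulus level.
#'
#' @param epochs An [epochs_set()].
#' @param window `c(start, end)` ms; must contain at least one sample of the
#'   time axis.
#' @return The corrected `epochs_set`.
#' @export
baseline_correct <- function(epochs, window = epochs$baseline_window_ms) {
  stopifnot(inherits(epochs, "epochs_set"))
  idx <- which(epochs$times_ms >= window[1] & epochs$times_ms <= window[2])
  if (!length(idx)) {
    abort(sprintf("baseline window [%g, %g] ms contains no samples", window[1], window[2]))
  }
  base <- apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(base) # recycles over the time dim
  epochs
}

#' Average epochs of one condition into an evoked field
#'
#' @param epochs An [epochs_set()].
#' @param condition Condition label to average.
#' @return `sensor x time` matrix with attribute `times_ms`.
#' @export
average_by_condition <- function(epochs, condition) {
  stopifnot(inherits(epochs, "epochs_set"))
  idx <- which(epochs$labels == condition)
  if (!length(idx)) abort(sprintf("no trials with condition '%s'", condition))
  ev <- apply(epochs$data[idx, , , drop = FALSE], c(2, 3), mean)
  attr(ev, "times_ms") <- epochs$times_ms
  ev
}

#' Deviant-minus-standard difference (mismatch) field
#'
#' Elementwise `deviant - standard`; positive values mean the deviant evoked
#' a stronger response. Accepts single-subject `sensor x time` matrices or
#' matched `subject x sensor x time` arrays.
#'
#' @param evoked_deviant,evoked_standard Matching evoked fields. When both
#'   carry a `times_ms` attribute the axes must agree.
#' @return The difference, same shape as the inputs.
#' @export
difference_field <- function(evoked_deviant, evoked_standard) {
  if (!identical(dim(evoked_deviant), dim(evoked_standard))) {
    abort("evoked fields have mismatched shapes")
  }
  td <- attr(evoked_deviant, "times_ms")
  ts <- attr(evoked_standard, "times_ms")
  if (!is.null(td) && !is.null(ts) && !isTRUE(all.equal(td, ts))) {
    abort("evoked fields have mismatched time axes")
  }
  out <- evoked_deviant - evoked_standard
  if (!is.null(td)) attr(out, "times_ms") <- td
  out
}

#' Build a per-subject contrast field from an evoked set
#'
#' The `word` contrast is word-deviant minus standard, `nonword` is
#' nonword-deviant minus standard, and `word_vs_nonword` is their difference
#' (equivalently word-deviant minus nonword-deviant), the field entering the
#' repeated-measures mismatch comparison.
#'
#' @param evoked An `evoked_set` from [simulate_evoked_dataset()].
#' @param contrast One of `"word"`, `"nonword"`, `"word_vs_nonword"`.
#' @return A `contrast_field`: list with `data` (`subject x sensor x time`),
#'   `times_ms`, `sensor_ids`, `subjects`, `contrast`.
#' @export
contrast_field <- function(evoked, contrast = c("word", "nonword", "word_vs_nonword")) {
  stopifnot(inherits(evoked, "evoked_set"))
  contrast <- match.arg(contrast)
  data <- switch(contrast,
    word = evoked$data$word_deviant - evoked$data$standard,
    nonword = evoked$data$nonword_deviant - evoked$data$standard,
    word_vs_nonword = evoked$data$word_deviant - evoked$data$nonword_deviant
  )
  structure(
    list(
      data = data, times_ms = evoked$times_ms,
      sensor_ids = evoked$sensors$sensors$sensor,
      subjects = evoked$subjects, contrast = contrast
    ),
    class = "contrast_field"
  )
}

#' Assemble a contrast field from an array
#'
#' Low-level constructor for simulated or externally supplied per-subject
#' difference fields.
#'
#' @param data `subject x sensor x time` array.
#' @param times_ms Time axis in ms.
#' @param sensor_ids Optional sensor identifiers.
#' @param subjects Optional subject identifiers.
#' @param contrast Contrast name.
#' @return A `contrast_field`.
#' @export
as_contrast_field <- function(data, times_ms,
                              sensor_ids = sprintf("S%03d", seq_len(dim(data)[2])),
                              subjects = sprintf("sub%03d", seq_len(dim(data)[1])),
                              contrast = "custom") {
  stopifnot(length(dim(data)) == 3L, length(times_ms) == dim(data)[3])
  structure(
    list(
      data = data, times_ms = as.numeric(times_ms),
      sensor_ids = sensor_ids, subjects = subjects, contrast = contrast
    ),
    class = "contrast_field"
  )
}

#' @export
print.contrast_field <- function(x, ...) {
  cat(sprintf(
    "<contrast_field '%s'> %d subjects x %d sensors x %d timepoints\n",
    x$contrast, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3]
  ))
  invisible(x)
}

#' @describeIn contrast_field Long tibble (subject, sensor, time_ms, value).
#' @param x A `contrast_field`.
#' @param ... Unused.
#' @method tidy contrast_field
#' @export
tidy.contrast_field <- function(x, ...) {
  d <- dim(x$data)
  tibble::tibble(
    subject = rep(x$subjects, times = d[2] * d[3]),
    sensor = rep(rep(x$sensor_ids, each = d[1]), times = d[3]),
    time_ms = rep(x$times_ms, each = d[1] * d[2]),
    value = as.vector(x$data)
  )
}

#' @method autoplot contrast_field
#' @export
autoplot.contrast_field <- function(object, ...) {
  grand <- apply(object$data, c(2, 3), mean)
  df <- tibble::tibble(
    sensor = rep(object$sensor_ids, times = length(object$times_ms)),
    time_ms = rep(object$times_ms, each = length(object$sensor_ids)),
    value = as.vector(grand)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$value, group = .data$sensor)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(
      title = sprintf("Grand-average %s contrast", object$contrast),
      x = "time (ms)", y = "field strength (a.u.)"
    ) +
    ggplot2::theme_minimal()
}
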