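#' Gaussian spatial weight map over a sensor array
#'
#' Smooth unimodal topography centred at a helmet-plane location, used to
#' give simulated evoked components a lateralized spatial footprint.
#'
#' @param sensors A `sensor_array`.
#' @param center Length-2 `c(x, y)` centre in layout units.
#' @param fwhm Full width at half maximum of the Gaussian, layout units.
#' @return Numeric weight per sensor in `[0, 1]` (1 at the centre).
#' @export
gaussian_map <- function(sensors, center, fwhm) {
  d2 <- (sensors$sensors$x - center[1])^2 + (sensors$sensors$y - center[2])^2
  exp(-4 * log(2) * d2 / fwhm^2)
}

#' Define one evoked component of the simulation forward model
#'
#' A component is a separable (spatial map) x (temporal kernel) bump added to
#' the evoked field of every condition that triggers it. Its subject-level
#' amplitude is `amplitude + sum_k beta_k * z(covariate_k)`, so covariates
#' can modulate component strength across the cohort.
#'
#' @param name Component name (e.g. `"p300_word"`).
#' @param conditions Character vector of trial conditions that trigger it.
#' @param window_ms `c(start, end)` of the temporal window in ms.
#' @param amplitude Base amplitude in field-strength units.
#' @param spatial_map Numeric weight per sensor (see [gaussian_map()]).
#' @param covariate_betas Named numeric vector: amplitude slope per z-scored
#'   cohort covariate (default none).
#' @param kernel Temporal kernel shape; only `"hanning"` is implemented (a
#'   raised-cosine bump over `window_ms`, peak 1 at the window centre).
#' @return An `effect_component` list.
#' @export
effect_component <- function(name, conditions, window_ms, amplitude, spatial_map,
                             covariate_betas = numeric(), kernel = "hanning") {
  stopifnot(length(window_ms) == 2L, window_ms[1] < window_ms[2], is.finite(amplitude))
  kernel <- match.arg(kernel)
  structure(
    list(
      name = name, conditions = conditions, window_ms = as.numeric(window_ms),
      amplitude = amplitude, spatial_map = spatial_map,
      covariate_betas = covariate_betas, kernel = kernel
    ),
    class = "effect_component"
  )
}

#' Bundle evoked components with the noise model
#'
#' @param components List of [effect_component()]s.
#' @param noise_sd Trial-level noise SD in field-strength units. Evoked-level
#'   noise scales as `noise_sd / sqrt(n_trials)` of the averaged condition.
#' @param spatial_noise_smoothing Neighbour-mixing coefficient in `[0, 1)`:
#'   each noise sample is mixed with the mean of its spatial neighbours to
#'   mimic the spatial correlation of real sensor noise.
#' @param temporal_noise_smoothing Half-width (samples) of a raised-cosine
#'   temporal smoother applied to the noise so it is band-limited; `0`
#'   disables it.
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(components, noise_sd = 15,
                        spatial_noise_smoothing = 0.3,
                        temporal_noise_smoothing = 2L) {
  if (noise_sd < 0) abort("'noise_sd' must be >= 0")
  if (spatial_noise_smoothing < 0 || spatial_noise_smoothing >= 1) {
    abort("'spatial_noise_smoothing' must be in [0, 1)")
  }
  structure(
    list(
      components = components, noise_sd = noise_sd,
      spatial_noise_smoothing = spatial_noise_smoothing,
      temporal_noise_smoothing = as.integer(temporal_noise_smoothing)
    ),
    class = "effect_spec"
  )
}

#' Default effect specification for a phonological oddball session
#'
#' Mimics the component structure reported for word/nonword mismatch fields
#' in children: an early auditory response common to all stimuli
#' (~100-160 ms), lateralized mismatch (N200-window, ~170-240 ms) responses
#' to the deviants, and later P300-window (~320-400 ms) responses, with the
#' word-deviant late component modulated by the subjective SES ladder
#' rating. Amplitudes are in arbitrary field-strength units (order of
#' femtotesla).
#'
#' @param sensors A `sensor_array`.
#' @param ses_beta Amplitude slope of the word P300-window component per SD
#'   of subjective SES.
#' @param noise_sd Trial-level noise SD.
#' @return An `effect_spec`.
#' @export
default_effect_spec <- function(sensors, ses_beta = 25, noise_sd = 150) {
  xr <- range(sensors$sensors$x)
  yr <- range(sensors$sensors$y)
  right <- c(xr[1] + 0.8 * diff(xr), yr[1] + 0.6 * diff(yr))
  left <- c(xr[1] + 0.2 * diff(xr), yr[1] + 0.6 * diff(yr))
  centre <- c(mean(xr), mean(yr))
  fw <- 0.35 * max(diff(xr), 1)
  effect_spec(
    components = list(
      effect_component("auditory_m100", c("standard", "word_deviant", "nonword_deviant"),
        c(80, 160), 50, gaussian_map(sensors, centre, fw)
      ),
      effect_component("n200_word", "word_deviant", c(177, 243), 30,
        gaussian_map(sensors, right, fw)
      ),
      effect_component("n200_nonword", "nonword_deviant", c(170, 229), 24,
        gaussian_map(sensors, right, fw)
      ),
      effect_component("p300_word", "word_deviant", c(317, 398), 35,
        gaussian_map(sensors, left, fw),
        covariate_betas = c(subjective_ses = ses_beta)
      ),
      effect_component("p300_nonword", "nonword_deviant", c(335, 401), 28,
        gaussian_map(sensors, left, fw)
      )
    ),
    noise_sd = noise_sd
  )
}

# Raised-cosine (Hanning) bump over [t0, t1], peak 1 at the window centre.
hanning_kernel <- function(times_ms, window_ms) {
  k <- numeric(length(times_ms))
  inside <- times_ms >= window_ms[1] & times_ms <= window_ms[2]
  u <- (times_ms[inside] - window_ms[1]) / diff(window_ms)
  k[inside] <- 0.5 - 0.5 * cos(2 * pi * u)
  k
}

# Deterministic sensor x time signal for one condition and one subject.
# `covariate_z` is a named vector of the subject's z-scored covariates.
condition_signal <- function(condition, spec, sensors, times_ms, covariate_z = numeric()) {
  sig <- matrix(0, nrow(sensors$sensors), length(times_ms))
  for (comp in spec$components) {
    if (!condition %in% comp$conditions) next
    amp <- comp$amplitude
    if (length(comp$covariate_betas)) {
      z <- covariate_z[names(comp$covariate_betas)]
      if (anyNA(z)) {
        abort(sprintf(
          "component '%s' references covariates missing from the cohort: %s",
          comp$name, paste(setdiff(names(comp$covariate_betas), names(covariate_z)), collapse = ", ")
        ))
      }
      amp <- amp + sum(comp$covariate_betas * z)
    }
    sig <- sig + amp * outer(comp$spatial_map, hanning_kernel(times_ms, comp$window_ms))
  }
  sig
}

# Spatially and temporally smoothed Gaussian noise, rescaled to `sd_target`.
smoothed_noise <- function(n_sensors, n_times, sd_target, adjacency,
                           alpha, half_width) {
  if (sd_target == 0) return(matrix(0, n_sensors, n_times))
  x <- matrix(rnorm(n_sensors * n_times), n_sensors, n_times)
  if (alpha > 0) {
    deg <- pmax(rowSums(adjacency), 1L)
    x <- (1 - alpha) * x + alpha * ((adjacency %*% x) / deg)
  }
  if (half_width > 0) {
    w <- 0.5 - 0.5 * cos(2 * pi * seq_len(2 * half_width + 1) / (2 * half_width + 2))
    w <- w / sum(w)
    x <- t(apply(x, 1, function(row) {
      sm <- stats::filter(row, w, sides = 2)
      ifelse(is.na(sm), row, as.numeric(sm))
    }))
  }
  x * (sd_target / pop_sd(as.numeric(x)))
}

#' Simulate per-condition evoked fields for a whole cohort
#'
#' Applies the forward model: for subject s and condition c the evoked field
#' is the sum over triggered components of
#' `(base + sum_k beta_k * z(x_sk)) * spatial_map %o% temporal_kernel`, plus
#' spatially smoothed Gaussian noise whose SD is the trial-level
#' `noise_sd / sqrt(n_trials(c))` — conditions averaged over more trials are
#' cleaner, as in a real oddball session. Ground-truth component masks are
#' attached for recovery tests.
#'
#' @param cohort Tibble from [simulate_cohort()].
#' @param protocol [oddball_protocol()]; supplies per-condition trial counts
#'   for the evoked noise scaling.
#' @param sensors A `sensor_array`.
#' @param spec An [effect_spec()].
#' @param epoch_window `c(start, end)` of the epoch in ms.
#' @param sfreq Sampling rate in Hz.
#' @param seed Optional integer seed.
#'
#' @return An `evoked_set`: per-condition `subject x sensor x time` arrays
#'   (`$data`), `$times_ms`, `$sensors`, `$subjects`, and `$truth` — one
#'   entry per component with its triggering conditions, covariate betas and
#'   logical sensor x time mask (sensors at >= half the map's peak weight,
#'   times inside the component window).
#' @export
simulate_evoked_dataset <- function(cohort, protocol, sensors, spec,
                                    epoch_window = c(-200, 1000),
                                    sfreq = 250, seed = NULL) {
  stopifnot(inherits(sensors, "sensor_array"), inherits(spec, "effect_spec"))
  if (sfreq <= 0) abort("'sfreq' must be > 0")
  times <- seq(epoch_window[1], epoch_window[2], by = 1000 / sfreq)
  for (comp in spec$components) {
    if (comp$window_ms[1] < epoch_window[1] || comp$window_ms[2] > epoch_window[2]) {
      abort(sprintf(
        "component '%s' window [%g, %g] ms lies outside the epoch [%g, %g] ms",
        comp$name, comp$window_ms[1], comp$window_ms[2], epoch_window[1], epoch_window[2]
      ))
    }
  }
  conditions <- c("standard", "word_deviant", "nonword_deviant")
  n_sub <- nrow(cohort)
  n_sens <- nrow(sensors$sensors)
  n_time <- length(times)

  cov_names <- unique(unlist(lapply(spec$components, function(c) names(c$covariate_betas))))
  zcov <- matrix(0, n_sub, 0)
  if (length(cov_names)) {
    missing <- setdiff(cov_names, names(cohort))
    if (length(missing)) {
      abort(paste0("cohort lacks covariates referenced by the effect spec: ",
                   paste(missing, collapse = ", ")))
    }
    zcov <- vapply(cov_names, function(nm) zscore_vec(as.numeric(cohort[[nm]]), nm),
                   numeric(n_sub))
    zcov <- matrix(zcov, n_sub, length(cov_names), dimnames = list(NULL, cov_names))
  }

  with_seed_(seed, {
    data <- lapply(conditions, function(cond) {
      sd_c <- if (spec$noise_sd > 0) spec$noise_sd / sqrt(protocol$counts[[cond]]) else 0
      arr <- array(0, c(n_sub, n_sens, n_time))
      for (s in seq_len(n_sub)) {
        zrow <- if (ncol(zcov)) zcov[s, ] else numeric()
        arr[s, , ] <- condition_signal(cond, spec, sensors, times, zrow) +
          smoothed_noise(n_sens, n_time, sd_c, sensors$adjacency,
                         spec$spatial_noise_smoothing, spec$temporal_noise_smoothing)
      }
      arr
    })
    names(data) <- conditions

    truth <- lapply(spec$components, function(comp) {
      sens_idx <- which(comp$spatial_map >= 0.5 * max(comp$spatial_map))
      time_idx <- which(times >= comp$window_ms[1] & times <= comp$window_ms[2])
      mask <- matrix(FALSE, n_sens, n_time)
      mask[sens_idx, time_idx] <- TRUE
      list(
        name = comp$name, conditions = comp$conditions,
        covariate_betas = comp$covariate_betas,
        sensor_idx = sens_idx, time_idx = time_idx, mask = mask
      )
    })
    names(truth) <- vapply(spec$components, `[[`, "", "name")

    structure(
      list(
        data = data, times_ms = times, sensors = sensors,
        subjects = cohort$subject_id, conditions = conditions,
        truth = truth, spec = spec, protocol = protocol
      ),
      class = "evoked_set"
    )
  })
}

#' @export
print.evoked_set <- function(x, ...) {
  cat(sprintf(
    "<evoked_set> %d subjects x %d sensors x %d timepoints (%g-%g ms), conditions: %s\n",
    length(x$subjects), nrow(x$sensors$sensors), length(x$times_ms),
    min(x$times_ms), max(x$times_ms), paste(x$conditions, collapse = ", ")
  ))
  invisible(x)
}
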