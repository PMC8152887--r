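#' Configuration for a full simulated oddball analysis run
#'
#' Gathers every tunable of the end-to-end pipeline; the global `seed`
#' propagates deterministic sub-seeds to every stochastic stage so a run is
#' reproducible from its manifest.
#'
#' @param n_subjects Cohort size (reference study: 71 full datasets).
#' @param protocol An [oddball_protocol()].
#' @param n_sensors,layout,neighbor_rule,k Sensor-array parameters
#'   (reference: 102 magnetometers).
#' @param cohort A [cohort_model()].
#' @param ses_beta,noise_sd Forwarded to [default_effect_spec()]; the effect
#'   spec itself is built against the sensor array at run time.
#' @param contrast_config [cluster_config()] for the word-vs-nonword
#'   sign-flip test (reference threshold 4).
#' @param glm_config [cluster_config()] for the per-regressor shuffle tests
#'   (reference threshold 2.8).
#' @param glm_regressors Covariate names entering the design (intercept is
#'   added by the builder).
#' @param sfreq Sampling rate, Hz.
#' @param epoch_window Epoch limits in ms.
#' @param seed Global integer seed.
#' @return A `run_config` list.
#' @export
run_config <- function(n_subjects = 71L,
                       protocol = oddball_protocol(),
                       n_sensors = 102L, layout = "rings",
                       neighbor_rule = "knn", k = 4L,
                       cohort = cohort_model(),
                       ses_beta = 25, noise_sd = 150,
                       contrast_config = cluster_config(4, seed = NULL),
                       glm_config = cluster_config(2.8, seed = NULL),
                       glm_regressors = c(
                         "wm_executive", "classic_iq", "verbal_stm_wm",
                         "attainment", "age_years", "equivalized_income",
                         "subjective_ses"
                       ),
                       sfreq = 250, epoch_window = c(-200, 1000),
                       seed = 1L) {
  structure(
    list(
      n_subjects = n_subjects, protocol = protocol,
      n_sensors = n_sensors, layout = layout,
      neighbor_rule = neighbor_rule, k = k,
      cohort = cohort, ses_beta = ses_beta, noise_sd = noise_sd,
      contrast_config = contrast_config, glm_config = glm_config,
      glm_regressors = glm_regressors,
      sfreq = sfreq, epoch_window = epoch_window, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

# Deterministic per-stage sub-seeds from the global seed (kept < 2^31).
stage_seed <- function(seed, offset) (as.integer(seed) * 101L + offset) %% 2147483629L

config_digest <- function(config) {
  list(
    n_subjects = config$n_subjects,
    protocol = config$protocol[c("n_trials", "ratio", "gap_range", "lead_in",
                                 "isi_ms", "stim_duration_ms")],
    sensors = list(n = config$n_sensors, layout = config$layout,
                   rule = config$neighbor_rule, k = config$k),
    ses_beta = config$ses_beta, noise_sd = config$noise_sd,
    contrast_config = unclass(config$contrast_config),
    glm_config = unclass(config$glm_config),
    glm_regressors = config$glm_regressors,
    sfreq = config$sfreq, epoch_window = config$epoch_window,
    seed = config$seed
  )
}

#' Simulate the raw artifacts of a run and write them to disk
#'
#' Generates the trial sequence, sensor array, cohort and per-condition
#' evoked fields under the config's seed and writes plain-text artifacts
#' (`cohort.tsv`, `trial_sequence.tsv`, `sensor_layout.tsv`, `config.yaml`)
#' plus the evoked arrays as `evoked.rds`. Identical seeds produce
#' byte-identical TSV outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Writable output directory (created if needed).
#' @return (Invisibly) a list with the in-memory `sequence`, `sensors`,
#'   `cohort`, `evoked` and the output paths.
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, mode = 2) != 0) {
    abort(sprintf("output directory '%s' is not writable", out_dir))
  }
  sequence <- simulate_trial_sequence(config$protocol, seed = stage_seed(config$seed, 1L))
  sensors <- build_sensor_array(config$n_sensors, config$layout,
                                config$neighbor_rule, k = config$k)
  cohort <- simulate_cohort(config$n_subjects, config$cohort,
                            seed = stage_seed(config$seed, 2L))
  spec <- default_effect_spec(sensors, ses_beta = config$ses_beta,
                              noise_sd = config$noise_sd)
  evoked <- simulate_evoked_dataset(cohort, config$protocol, sensors, spec,
                                    epoch_window = config$epoch_window,
                                    sfreq = config$sfreq,
                                    seed = stage_seed(config$seed, 3L))
  cohort_flat <- dplyr::mutate(
    cohort,
    child_ages = vapply(.data$child_ages, paste, "", collapse = ",")
  )
  paths <- list(
    cohort = file.path(out_dir, "cohort.tsv"),
    sequence = file.path(out_dir, "trial_sequence.tsv"),
    layout = file.path(out_dir, "sensor_layout.tsv"),
    evoked = file.path(out_dir, "evoked.rds"),
    config = file.path(out_dir, "config.yaml")
  )
  write_tsv_plain(cohort_flat, paths$cohort)
  write_tsv_plain(sequence, paths$sequence)
  write_tsv_plain(tidy(sensors), paths$layout)
  saveRDS(evoked, paths$evoked, version = 2)
  yaml::write_yaml(config_digest(config), paths$config)
  invisible(list(
    sequence = sequence, sensors = sensors, cohort = cohort,
    evoked = evoked, paths = paths
  ))
}

write_tsv_plain <- function(df, path) {
  utils::write.table(as.data.frame(df), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
}

#' Construct the GLM covariate table from a simulated cohort
#'
#' Reduces the eight-measure battery to three varimax-rotated cognitive
#' factors (working memory & executive, classic IQ, verbal STM & WM — fixed
#' at three components, the plausible-factor choice for this battery) and
#' the two attainment measures to a single attainment factor, then appends
#' age in years, OECD-equivalized household income and the subjective SES
#' ladder rating.
#'
#' @param cohort A [simulate_cohort()] tibble.
#' @param seed Seed for the parallel-analysis nulls inside the factor fits.
#' @return Tibble with `subject_id` and the seven covariates; the two
#'   `factor_model` fits are attached as attributes `cognitive_model` and
#'   `attainment_model`.
#' @export
build_covariate_table <- function(cohort, seed = NULL) {
  batt <- battery_columns(cohort)
  cog <- fit_factor_model(cohort[batt], n_factors = 3L, seed = seed)
  wj <- intersect(c("wj_reading", "wj_mathematics"), batt)
  att <- fit_factor_model(cohort[wj], n_factors = 1L)
  out <- tibble::tibble(
    subject_id = cohort$subject_id,
    wm_executive = cog$scores[, 1],
    classic_iq = cog$scores[, 2],
    verbal_stm_wm = cog$scores[, 3],
    attainment = att$scores[, 1],
    age_years = cohort$age_years,
    equivalized_income = equivalize_income(
      cohort$income_raw, cohort$n_adults, cohort$child_ages
    ),
    subjective_ses = cohort$subjective_ses
  )
  attr(out, "cognitive_model") <- cog
  attr(out, "attainment_model") <- att
  out
}

#' Run the whole analysis end to end
#'
#' Executes simulate -> contrast fields -> behavioral factors -> design
#' matrix -> mass OLS GLM -> cluster permutation inference, writes the
#' contrast-test table, per-regressor GLM cluster tables and a JSON run
#' manifest (config echo, seed, per-stage timings), and returns all fitted
#' objects. Any stage error is rethrown tagged with the stage name.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @param regressors Regressors to permutation-test (default: every
#'   non-intercept regressor in the design).
#' @return (Invisibly) list with `simulated`, `contrast` (`word`), the
#'   sign-flip `contrast_test`, `covariates`, `design`, `glm_fit`,
#'   `glm_tests` (named list), and `manifest`.
#' @export
run_full_pipeline <- function(config, out_dir, regressors = NULL) {
  stopifnot(inherits(config, "run_config"))
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  sim <- stage("simulate", run_simulate(config, out_dir))
  word <- stage("contrasts", contrast_field(sim$evoked, "word"))
  mismatch <- stage("contrasts_diff", contrast_field(sim$evoked, "word_vs_nonword"))

  cc <- config$contrast_config
  cc$seed <- stage_seed(config$seed, 4L)
  contrast_test <- stage(
    "contrast_test",
    signflip_contrast_test(mismatch, sim$sensors, cc)
  )

  covariates <- stage("factors", build_covariate_table(sim$cohort,
                                                       seed = stage_seed(config$seed, 5L)))
  design <- stage("design", build_design_matrix(covariates, config$glm_regressors))
  glm_fit <- stage("glm", fit_ols(design, word))

  if (is.null(regressors)) regressors <- setdiff(design$regressor_names, "intercept")
  glm_tests <- list()
  for (i in seq_along(regressors)) {
    gc_ <- config$glm_config
    gc_$seed <- stage_seed(config$seed, 10L + i)
    glm_tests[[regressors[i]]] <- stage(
      paste0("glm_test_", regressors[i]),
      regressor_shuffle_glm_test(design, word, regressors[i], sim$sensors, gc_)
    )
  }

  write_tsv_plain(cluster_table(contrast_test, all = TRUE),
                  file.path(out_dir, "contrast_clusters.tsv"))
  glm_table <- purrr::imap_dfr(glm_tests, function(tst, nm) {
    dplyr::mutate(cluster_table(tst, all = TRUE), regressor = nm, .before = 1)
  })
  write_tsv_plain(glm_table, file.path(out_dir, "glm_clusters.tsv"))
  memberships <- purrr::map(glm_tests, function(tst) {
    purrr::map(tst$clusters$members, function(m) {
      list(sensors = tst$sensor_ids[m[, 1]], time_idx = unname(m[, 2]))
    })
  })
  jsonlite::write_json(memberships, file.path(out_dir, "glm_cluster_members.json"),
                       auto_unbox = TRUE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("oddballmeg")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = config_digest(config),
    timings_s = timings
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(
    simulated = sim, contrast = word, mismatch = mismatch,
    contrast_test = contrast_test, covariates = covariates,
    design = design, glm_fit = glm_fit, glm_tests = glm_tests,
    manifest = manifest
  ))
}
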