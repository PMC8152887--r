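#' Family-wise error calibration of the regressor-shuffle cluster test
#'
#' Simulates pure-noise datasets with an honest design (a simulated cohort's
#' full covariate table behind an intercept) and runs the regressor-shuffle
#' cluster permutation test on one covariate per dataset. Under the null the
#' fraction of datasets yielding any significant cluster estimates the
#' empirical family-wise error rate, which max-statistic inference should
#' hold at or below the nominal alpha.
#'
#' @param n_datasets Number of null datasets.
#' @param n_subjects Subjects per dataset.
#' @param n_sensors,n_times Grid size (sensors laid out as a near-square
#'   grid with 4-neighbourhood adjacency).
#' @param cluster_forming_t Cluster-forming |t| threshold.
#' @param n_permutations Permutations per dataset.
#' @param alpha Significance level.
#' @param target Covariate under test (any column of the covariate table).
#' @param seed Integer seed; dataset d uses deterministic sub-seeds derived
#'   from it.
#' @return A list: `rate` (empirical FWER), `hits` (logical per dataset),
#'   `binomial_se` (at the nominal alpha), and the condition parameters.
#' @examples
#' \donttest{
#' cal <- fwer_calibration(n_datasets = 20, n_permutations = 200, seed = 1)
#' cal$rate
#' }
#' @export
fwer_calibration <- function(n_datasets = 200L, n_subjects = 30L,
                             n_sensors = 20L, n_times = 50L,
                             cluster_forming_t = 2.8,
                             n_permutations = 500L, alpha = 0.05,
                             target = "subjective_ses", seed = 1L) {
  sensors <- build_sensor_array(n_sensors, layout = "grid")
  hits <- vapply(seq_len(n_datasets), function(d) {
    base <- stage_seed(seed, 7L * d)
    cohort <- simulate_cohort(n_subjects, seed = base)
    covariates <- build_covariate_table(cohort, seed = base + 1L)
    design <- build_design_matrix(covariates, setdiff(names(covariates), "subject_id"))
    noise <- withr::with_seed(base + 2L, {
      array(rnorm(n_subjects * n_sensors * n_times), c(n_subjects, n_sensors, n_times))
    })
    cf <- as_contrast_field(noise,
      times_ms = seq(0, by = 4, length.out = n_times),
      subjects = cohort$subject_id
    )
    res <- regressor_shuffle_glm_test(
      design, cf, target, sensors,
      cluster_config(cluster_forming_t, n_permutations, alpha = alpha,
                     seed = base + 3L)
    )
    any(res$clusters$significant)
  }, logical(1))
  list(
    rate = mean(hits), hits = hits,
    binomial_se = sqrt(alpha * (1 - alpha) / n_datasets),
    n_datasets = n_datasets, n_subjects = n_subjects,
    n_sensors = n_sensors, n_times = n_times,
    cluster_forming_t = cluster_forming_t,
    n_permutations = n_permutations, alpha = alpha, target = target
  )
}
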