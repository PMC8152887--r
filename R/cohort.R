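#' Default behavioral battery loading matrix
#'
#' A planted 3-factor simple structure over the eight age-standardized
#' battery measures (working-memory, IQ and attainment style scores). Rows
#' are variables, columns latent factors; unique variances are set so each
#' observed variable has unit variance before rescaling.
#'
#' @return 8 x 3 numeric matrix with dimnames.
#' @export
default_battery_loadings <- function() {
  vars <- c(
    "awma_digit_recall", "awma_dot_matrix", "awma_mr_x", "awma_backward_digit",
    "wasi_vocabulary", "wasi_matrix_reasoning", "wj_reading", "wj_mathematics"
  )
  L <- matrix(0, 8, 3, dimnames = list(vars, c("F1", "F2", "F3")))
  L["awma_dot_matrix", 1] <- 0.75
  L["awma_mr_x", 1] <- 0.70
  L["wasi_matrix_reasoning", 1] <- 0.65
  L["wasi_vocabulary", 2] <- 0.75
  L["wj_reading", 2] <- 0.70
  L["wj_mathematics", 2] <- 0.65
  L["awma_digit_recall", 3] <- 0.75
  L["awma_backward_digit", 3] <- 0.70
  L
}

#' Describe the covariate-generating model for a simulated cohort
#'
#' Marginals and correlation structure for a socioeconomically diverse child
#' cohort. Household income is log-normal with mean £24,313 and SD £12,261
#' per year; the subjective socioeconomic-status ladder (1-10 rungs) is an
#' income-correlated latent normal cut into population deciles; ages are
#' uniform over roughly 7-12.75 years. Behavioral scores follow a planted
#' low-rank factor model: `scores = latents %*% t(loadings) + noise`, scaled
#' to an age-standardized-like mean 100 / SD 15 metric.
#'
#' @param income_mean,income_sd Target mean and SD of raw household income in
#'   currency units per year (log-normal marginal matched by moments).
#' @param ses_income_cor Correlation between log income and the latent ladder
#'   rating.
#' @param age_range Age range in years.
#' @param loadings Variable x factor loading matrix for the battery
#'   (rows named after battery columns).
#' @param score_noise_sd Unique-noise SD per variable. The default `NULL`
#'   sets `sqrt(1 - communality)` per row so observed variables have unit
#'   variance; pass `0` for a noiseless (exact low-rank) battery.
#' @param score_mean,score_sd Rescaling of the standardized battery scores.
#'
#' @return A `cohort_model` list.
#' @export
cohort_model <- function(income_mean = 24313,
                         income_sd = 12261,
                         ses_income_cor = 0.5,
                         age_range = c(6.97, 12.78),
                         loadings = default_battery_loadings(),
                         score_noise_sd = NULL,
                         score_mean = 100,
                         score_sd = 15) {
  if (abs(ses_income_cor) > 1) abort("'ses_income_cor' must be a valid correlation in [-1, 1]")
  if (is.null(rownames(loadings))) abort("'loadings' must have variable row names")
  if (any(rowSums(loadings^2) > 1 + 1e-8)) {
    abort("invalid correlation structure: communalities exceed 1 (loadings too large)")
  }
  cv2 <- (income_sd / income_mean)^2
  sdlog <- sqrt(log1p(cv2))
  meanlog <- log(income_mean) - sdlog^2 / 2
  if (is.null(score_noise_sd)) {
    score_noise_sd <- sqrt(pmax(0, 1 - rowSums(loadings^2)))
  } else if (length(score_noise_sd) == 1L) {
    score_noise_sd <- rep(score_noise_sd, nrow(loadings))
  }
  structure(
    list(
      income_meanlog = meanlog, income_sdlog = sdlog,
      income_mean = income_mean, income_sd = income_sd,
      ses_income_cor = ses_income_cor, age_range = age_range,
      loadings = loadings, score_noise_sd = score_noise_sd,
      score_mean = score_mean, score_sd = score_sd
    ),
    class = "cohort_model"
  )
}

#' Simulate a cohort of subjects with covariates and a planted battery
#'
#' Generates one row per subject: demographic and socioeconomic covariates
#' (age, raw household income, household composition, subjective SES ladder
#' rating) plus the behavioral battery columns named in the model's loading
#' matrix. The latent factor scores and the generating loadings are attached
#' as attributes `latent_scores` and `loadings` so downstream factor-recovery
#' can be checked against ground truth.
#'
#' @param n_subjects Number of subjects.
#' @param model A [cohort_model()].
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `subject_id`, `age_years`, `income_raw`,
#'   `n_adults`, `child_ages` (list-column of the household's children's
#'   ages, the scanned child included), `subjective_ses` (integer 1-10) and
#'   one column per battery variable.
#' @examples
#' cohort <- simulate_cohort(71, seed = 1)
#' mean(cohort$income_raw)
#' @export
simulate_cohort <- function(n_subjects, model = cohort_model(), seed = NULL) {
  n_subjects <- stopifnot_scalar_count(n_subjects, "n_subjects", min = 1L)
  stopifnot(inherits(model, "cohort_model"))
  with_seed_(seed, {
    age <- runif(n_subjects, model$age_range[1], model$age_range[2])
    log_inc <- rnorm(n_subjects, model$income_meanlog, model$income_sdlog)
    income <- exp(log_inc)
    rho <- model$ses_income_cor
    ses_latent <- rho * (log_inc - model$income_meanlog) / model$income_sdlog +
      sqrt(1 - rho^2) * rnorm(n_subjects)
    ses <- pmin(10L, pmax(1L, as.integer(ceiling(10 * pnorm(ses_latent)))))
    n_adults <- sample(1:2, n_subjects, replace = TRUE, prob = c(0.25, 0.75))
    n_children <- sample(1:3, n_subjects, replace = TRUE, prob = c(0.35, 0.45, 0.20))
    child_ages <- lapply(seq_len(n_subjects), function(i) {
      sibs <- if (n_children[i] > 1L) sample(0:16, n_children[i] - 1L, replace = TRUE) else integer()
      c(floor(age[i]), sibs)
    })

    k <- ncol(model$loadings)
    latents <- matrix(rnorm(n_subjects * k), n_subjects, k,
      dimnames = list(NULL, colnames(model$loadings))
    )
    noise <- matrix(rnorm(n_subjects * nrow(model$loadings)), n_subjects) %*%
      diag(model$score_noise_sd, nrow(model$loadings))
    battery <- latents %*% t(model$loadings) + noise
    battery <- model$score_mean + model$score_sd * battery
    colnames(battery) <- rownames(model$loadings)

    out <- tibble::tibble(
      subject_id = sprintf("sub%03d", seq_len(n_subjects)),
      age_years = age,
      income_raw = income,
      n_adults = n_adults,
      child_ages = child_ages,
      subjective_ses = ses
    )
    out <- dplyr::bind_cols(out, tibble::as_tibble(battery))
    attr(out, "latent_scores") <- latents
    attr(out, "loadings") <- model$loadings
    class(out) <- c("cohort", class(out))
    out
  })
}

#' Battery column names of a cohort
#' @param cohort A cohort tibble from [simulate_cohort()].
#' @return Character vector of behavioral battery columns.
#' @export
battery_columns <- function(cohort) {
  ld <- attr(cohort, "loadings")
  if (!is.null(ld)) return(rownames(ld))
  setdiff(
    names(cohort),
    c("subject_id", "age_years", "income_raw", "n_adults", "child_ages", "subjective_ses")
  )
}
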