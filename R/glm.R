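#' Build the subject-level design matrix
#'
#' Prepends an all-ones intercept (the group-mean regressor) to the named
#' covariate columns, z-scores every covariate (population SD), and checks
#' full column rank. For the reference analysis the covariates are the three
#' cognitive factor scores, the attainment factor, age in years, equivalized
#' income and subjective SES — a `n_subjects x 8` matrix.
#'
#' @param covariates Data frame with one row per subject containing all
#'   columns named in `regressors` (no missing values), plus optionally a
#'   `subject_id` column used for alignment.
#' @param regressors Character vector of covariate column names, in design
#'   order.
#' @return A `design_matrix`: `X` (numeric matrix, first column `intercept`),
#'   `regressor_names`, `z_flags`, `subjects`.
#' @examples
#' cov <- data.frame(a = rnorm(10), b = rnorm(10))
#' build_design_matrix(cov, c("a", "b"))$X |> dim()  # 10 x 3
#' @export
build_design_matrix <- function(covariates, regressors = setdiff(names(covariates), "subject_id")) {
  covariates <- as.data.frame(covariates)
  missing <- setdiff(regressors, names(covariates))
  if (length(missing)) {
    abort(paste0("covariate table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  n <- nrow(covariates)
  cols <- lapply(regressors, function(nm) {
    col <- as.numeric(covariates[[nm]])
    if (anyNA(col)) abort(sprintf("covariate '%s' contains missing values", nm))
    zscore_vec(col, nm)
  })
  X <- cbind(intercept = rep(1, n), do.call(cbind, c(cols, list(deparse.level = 0))))
  colnames(X) <- c("intercept", regressors)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    abort(paste0(
      "design matrix is rank deficient (collinear column(s): ",
      paste(bad, collapse = ", "), ")"
    ))
  }
  structure(
    list(
      X = X,
      regressor_names = colnames(X),
      z_flags = c(FALSE, rep(TRUE, length(regressors))),
      subjects = if ("subject_id" %in% names(covariates)) covariates$subject_id else NULL
    ),
    class = "design_matrix"
  )
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf(
    "<design_matrix> %d x %d (%s)\n",
    nrow(x$X), ncol(x$X), paste(x$regressor_names, collapse = ", ")
  ))
  invisible(x)
}

#' @describeIn build_design_matrix Design as a tibble, one column per
#'   regressor.
#' @param x A `design_matrix`.
#' @param ... Unused.
#' @method tidy design_matrix
#' @export
tidy.design_matrix <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$X))
  if (!is.null(x$subjects)) out <- dplyr::bind_cols(tibble::tibble(subject_id = x$subjects), out)
  out
}

# Core mass-OLS solve shared by fit_ols() and the permutation engine.
# Y: n x P response matrix (points as columns). Returns per-regressor beta,
# se, t (p x P matrices), dof and residual variance (length P).
ols_maps <- function(X, Y) {
  n <- nrow(X)
  p <- ncol(X)
  qrX <- qr(X)
  beta <- qr.coef(qrX, Y)
  resid <- Y - X %*% beta
  dof <- n - p
  sigma2 <- colSums(resid^2) / dof
  xtx_inv_diag <- diag(solve(crossprod(X)))
  se <- sqrt(outer(xtx_inv_diag, sigma2))
  tval <- beta / se
  list(beta = beta, se = se, t = tval, dof = dof, sigma2 = sigma2)
}

#' Fit the mass-univariate OLS GLM over sensor x time
#'
#' Ordinary least squares at every (sensor, timepoint) of a per-subject
#' contrast field, all points solved in one matrix operation. Emits
#' per-regressor beta, standard-error and t maps with
#' `dof = n_subjects - n_regressors`.
#'
#' @param design A [build_design_matrix()] result.
#' @param contrasts A `contrast_field` with subjects aligned to the design
#'   (checked by id when both carry ids).
#' @return A `glm_result`: `betas`, `standard_errors`, `t_values`
#'   (`regressor x sensor x time` arrays), `residual_variance`
#'   (`sensor x time`), `dof`, axes, names.
#' @export
fit_ols <- function(design, contrasts) {
  stopifnot(inherits(design, "design_matrix"), inherits(contrasts, "contrast_field"))
  X <- design$X
  d <- dim(contrasts$data)
  if (d[1] != nrow(X)) {
    abort(sprintf("design has %d subjects but the contrast field has %d", nrow(X), d[1]))
  }
  if (!is.null(design$subjects) && !is.null(contrasts$subjects) &&
      !identical(as.character(design$subjects), as.character(contrasts$subjects))) {
    abort("subject ids in the design and contrast field are misaligned")
  }
  if (nrow(X) <= ncol(X)) {
    abort(sprintf(
      "need more subjects (%d) than regressors (%d) for OLS", nrow(X), ncol(X)
    ))
  }
  Y <- matrix(contrasts$data, nrow = d[1]) # subject x (sensor*time), column-major
  fit <- ols_maps(X, Y)
  p <- ncol(X)
  shape <- c(p, d[2], d[3])
  dn <- list(design$regressor_names, contrasts$sensor_ids, NULL)
  structure(
    list(
      betas = array(fit$beta, shape, dimnames = dn),
      standard_errors = array(fit$se, shape, dimnames = dn),
      t_values = array(fit$t, shape, dimnames = dn),
      residual_variance = matrix(fit$sigma2, d[2], d[3]),
      dof = fit$dof,
      regressor_names = design$regressor_names,
      sensor_ids = contrasts$sensor_ids,
      times_ms = contrasts$times_ms,
      n_subjects = d[1]
    ),
    class = "glm_result"
  )
}

#' @export
print.glm_result <- function(x, ...) {
  cat(sprintf(
    "<glm_result> %d regressors x %d sensors x %d timepoints, dof = %d\n",
    dim(x$t_values)[1], dim(x$t_values)[2], dim(x$t_values)[3], x$dof
  ))
  invisible(x)
}

#' Extract one regressor's t map
#' @param fit A `glm_result`.
#' @param regressor Regressor name or index.
#' @return `sensor x time` matrix of t values.
#' @export
t_map <- function(fit, regressor) {
  stopifnot(inherits(fit, "glm_result"))
  if (is.character(regressor) && !regressor %in% fit$regressor_names) {
    abort(sprintf(
      "unknown regressor '%s' (available: %s)", regressor,
      paste(fit$regressor_names, collapse = ", ")
    ))
  }
  m <- fit$t_values[regressor, , ]
  attr(m, "times_ms") <- fit$times_ms
  m
}

#' @describeIn fit_ols Long tibble (regressor, sensor, time_ms, beta, se, t).
#' @param x A `glm_result`.
#' @param ... Unused.
#' @method tidy glm_result
#' @export
tidy.glm_result <- function(x, ...) {
  d <- dim(x$betas)
  tibble::tibble(
    regressor = rep(x$regressor_names, times = d[2] * d[3]),
    sensor = rep(rep(x$sensor_ids, each = d[1]), times = d[3]),
    time_ms = rep(x$times_ms, each = d[1] * d[2]),
    beta = as.vector(x$betas),
    se = as.vector(x$standard_errors),
    t = as.vector(x$t_values)
  )
}

#' @describeIn fit_ols One row per regressor with the peak |t| and its
#'   location.
#' @method glance glm_result
#' @export
glance.glm_result <- function(x, ...) {
  purrr::map_dfr(seq_along(x$regressor_names), function(j) {
    tm <- x$t_values[j, , ]
    peak <- which(abs(tm) == max(abs(tm)), arr.ind = TRUE)[1, ]
    tibble::tibble(
      regressor = x$regressor_names[j],
      peak_t = tm[peak[1], peak[2]],
      peak_sensor = x$sensor_ids[peak[1]],
      peak_time_ms = x$times_ms[peak[2]],
      dof = x$dof,
      n_subjects = x$n_subjects
    )
  })
}

#' Two-sided critical t value
#'
#' Student t critical value for a two-tailed test, `qt(1 - alpha/2, dof)`;
#' e.g. alpha 0.05 at 70 degrees of freedom gives 1.99, which rounds to the
#' conventionally quoted critical t of 2 for a 71-subject design.
#'
#' @param alpha Two-sided error probability.
#' @param dof Degrees of freedom.
#' @return Scalar critical value.
#' @export
critical_t <- function(alpha = 0.05, dof) qt(1 - alpha / 2, dof)
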