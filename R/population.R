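# Virtual-patient sampling from typical values + log-normal BSV, and the
# proportional residual-error model used for synthetic observations.

.param_names <- c("v1", "v2", "v3", "cl1", "q1", "q2", "pc")

#' Sample virtual patients from a population specification
#'
#' Draws `n` individual parameter sets. Each parameter with a listed BSV is
#' log-normal around its typical value: `P_i = TV * exp(eta_i)` with
#' `eta_i ~ N(0, omega^2)` and `omega^2 = log(1 + (CV/100)^2)`, so the
#' typical value is the exact median and CV the exact coefficient of
#' variation of the sampling distribution. Parameters without BSV are fixed
#' at the typical value. Draws are independent across parameters and
#' subjects.
#'
#' @param spec A [pop_spec()] object.
#' @param n Number of virtual patients, `>= 1`.
#' @param seed Optional integer seed for reproducibility.
#' @return A data.frame with columns `id, v1, v2, v3, cl1, q1, q2, pc`;
#'   one row per virtual patient. All values strictly positive.
#' @examples
#' cohort <- sample_individuals(pop_spec(), 5, seed = 1)
#' @export
sample_individuals <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "pop_spec"))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("sample_individuals: 'n' must be >= 1", call. = FALSE)
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  out <- data.frame(id = seq_len(n))
  for (nm in .param_names) {
    tv <- spec$typical[[nm]]
    cv <- if (nm %in% names(spec$bsv_cv)) spec$bsv_cv[[nm]] else 0
    out[[nm]] <- if (cv > 0) {
      omega <- sqrt(log(1 + (cv / 100)^2))
      tv * exp(rnorm(n, 0, omega))
    } else rep(tv, n)
  }
  out
}

# pk_params for row i of a sampled cohort, with scenario drainage attached.
.cohort_params <- function(cohort, i, drainage_ml_day = 0,
                           drainage_as_rate_constant = FALSE) {
  pk_params(v1 = cohort$v1[i], v2 = cohort$v2[i], v3 = cohort$v3[i],
            cl1 = cohort$cl1[i], q1 = cohort$q1[i], q2 = cohort$q2[i],
            pc = cohort$pc[i], drainage_ml_day = drainage_ml_day,
            drainage_as_rate_constant = drainage_as_rate_constant)
}

#' Apply proportional residual error to model predictions
#'
#' Observation model `y = c * (1 + eps)`, `eps ~ N(0, (CV/100)^2)`,
#' truncated at zero so observed concentrations are never negative. Used
#' only when generating synthetic observations and in predictive checks;
#' PTA simulation operates on the error-free model predictions.
#'
#' @param conc Numeric vector of model-predicted concentrations (mg/L), or
#'   a [conc_profile()] (both matrices perturbed independently).
#' @param residual_cv Proportional residual error CV%, `>= 0`.
#' @param seed Optional integer seed.
#' @return Object of the same shape as `conc` with noisy concentrations.
#' @export
apply_residual_error <- function(conc, residual_cv, seed = NULL) {
  if (!is.numeric(residual_cv) || length(residual_cv) != 1L ||
      !is.finite(residual_cv) || residual_cv < 0)
    stop("apply_residual_error: 'residual_cv' must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sdv <- residual_cv / 100
  if (inherits(conc, "conc_profile")) {
    conc$conc_plasma <- pmax(conc$conc_plasma *
                               (1 + rnorm(length(conc$conc_plasma), 0, sdv)), 0)
    conc$conc_csf <- pmax(conc$conc_csf *
                            (1 + rnorm(length(conc$conc_csf), 0, sdv)), 0)
    conc$amounts <- NULL  # no longer consistent with concentrations
    return(conc)
  }
  pmax(conc * (1 + rnorm(length(conc), 0, sdv)), 0)
}

#' Export a virtual cohort as CSV
#' @param cohort Data.frame from [sample_individuals()].
#' @param path Output CSV path.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
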