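# Visual predictive check: percentile curves of the observations compared
# with simulation-based bands from replicate datasets generated under the
# study design (BSV + proportional residual error).

#' Visual predictive check
#'
#' Simulates `n_sim` replicate datasets at the observation design of
#' `data` (same subjects' dosing histories, sampling times and drainage
#' covariates), drawing new individual parameters from `spec` and new
#' proportional residual errors for each replicate. Observed and simulated
#' 5th/50th/95th percentile curves are computed per matrix within bins of
#' time after the start of the sampled dose, and the simulation spread
#' yields a 95% confidence band for each percentile curve.
#'
#' @param data A `study_data` or rectangular data.frame (needs `INTERVAL`
#'   inference: the time after the last dose is computed from each
#'   subject's dosing rows).
#' @param spec A [pop_spec()] describing the simulation model (e.g. the
#'   published population, or [fitted_params()] wrapped in a `pop_spec`).
#' @param n_sim Number of replicate datasets (1000 in the original
#'   analysis).
#' @param seed Integer seed.
#' @param probs Percentiles of interest.
#' @return A data.frame of class `pk_vpc` with columns `cmt, time, prob,
#'   observed, sim_median, sim_lower, sim_upper, n_obs`.
#' @export
vpc <- function(data, spec, n_sim = 1000, seed = NULL,
                probs = c(0.05, 0.5, 0.95)) {
  stopifnot(inherits(spec, "pop_spec"))
  df <- if (inherits(data, "study_data")) data$data else data
  subjects <- Filter(Negate(is.null), .parse_subjects(df))
  if (!is.null(seed)) set.seed(seed)

  # time after start of the dose preceding each observation
  tad <- lapply(subjects, function(s)
    vapply(s$times, function(t) t - max(s$segs$a[s$segs$rate > 0 &
                                                   s$segs$a <= t]),
           numeric(1)))
  bin <- unlist(lapply(seq_along(subjects), function(k)
    round(tad[[k]], 2)), use.names = FALSE)
  cmt <- unlist(lapply(subjects, `[[`, "cmt"), use.names = FALSE)
  dv <- unlist(lapply(subjects, `[[`, "dv"), use.names = FALSE)
  key <- paste(cmt, bin)
  groups <- sort(unique(key))

  pct <- function(values) {
    g <- split(values, key)[groups]
    t(vapply(g, quantile, numeric(length(probs)), probs = probs,
             na.rm = TRUE))
  }
  obs_pct <- pct(dv)

  nsub <- length(subjects)
  sims <- array(NA_real_, c(length(groups), length(probs), n_sim))
  for (r in seq_len(n_sim)) {
    cohort <- sample_individuals(spec, nsub, seed = NULL)
    sim_dv <- unlist(lapply(seq_along(subjects), function(k) {
      s <- subjects[[k]]
      p <- .cohort_params(cohort, k, drainage_ml_day = s$drain)
      A <- pk_system_matrix(p)
      amt <- .sim_piecewise(A, .pk_eig(A), s$segs, s$times)
      pred <- ifelse(s$cmt == 1, amt[1, ] / p$v1, amt[2, ] / p$v2)
      apply_residual_error(pred, spec$residual_cv)
    }), use.names = FALSE)
    sims[, , r] <- pct(sim_dv)
  }

  out <- do.call(rbind, lapply(seq_along(groups), function(gi) {
    parts <- strsplit(groups[gi], " ")[[1]]
    do.call(rbind, lapply(seq_along(probs), function(pi) {
      sp <- sims[gi, pi, ]
      data.frame(cmt = as.integer(parts[1]), time = as.numeric(parts[2]),
                 prob = probs[pi], observed = obs_pct[gi, pi],
                 sim_median = median(sp),
                 sim_lower = quantile(sp, 0.025),
                 sim_upper = quantile(sp, 0.975),
                 n_obs = sum(key == groups[gi]))
    }))
  }))
  rownames(out) <- NULL
  attr(out, "n_sim") <- n_sim
  class(out) <- c("pk_vpc", "data.frame")
  out
}

#' @export
plot.pk_vpc <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  for (k in 1:2) {
    g <- x[x$cmt == k, ]
    if (!nrow(g)) next
    plot(range(g$time), range(c(g$observed, g$sim_lower, g$sim_upper)),
         type = "n", xlab = "Time after dose (h)",
         ylab = "Concentration (mg/L)",
         main = c("Plasma", "CSF")[k])
    for (pr in unique(g$prob)) {
      gp <- g[g$prob == pr, ]
      gp <- gp[order(gp$time), ]
      polygon(c(gp$time, rev(gp$time)), c(gp$sim_lower, rev(gp$sim_upper)),
              col = adjustcolor("steelblue", 0.3), border = NA)
      lines(gp$time, gp$observed, col = "firebrick",
            lty = if (pr == 0.5) 1 else 2)
    }
  }
  invisible(x)
}

#' Export VPC bands as tidy CSV
#' @param v A `pk_vpc` object.
#' @param path Output CSV path.
#' @param header Optional `#`-prefixed comment lines.
#' @export
write_vpc <- function(v, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.csv(v, con, row.names = FALSE)
  invisible(path)
}
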