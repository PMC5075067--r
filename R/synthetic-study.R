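# Synthetic sparse-sampling trial generator emulating the clinical study
# design: 82 patients on 1 g q8h / 1 g q6h / 2 g q8h (42/19/21), paired
# plasma + CSF samples after the fourth dose at two nominal-time schedules,
# CSF drainage ~ truncated Normal(126, 81) mL/day on [0, 350].

#' Study design specification
#'
#' Defaults reproduce the clinical study's structure: 82 patients split
#' 42/19/21 across 1 g q8h, 1 g q6h and 2 g q8h (all infused at 1 g/h);
#' paired plasma and CSF samples drawn around the fourth dose; two
#' sampling-time groups (40/42 split): group 1 at mid-infusion and 10 min,
#' 2 h and 4 h after the end of infusion; group 2 at the end of infusion,
#' 1 h and 3 h after it, and immediately before the next dose. Demographics
#' are truncated normals with the published moments; serum creatinine is
#' back-solved from a creatinine-clearance distribution via Cockcroft-Gault.
#'
#' @param n_patients Total number of patients.
#' @param regimens Named list of [regimen()] objects.
#' @param regimen_split Integer counts per regimen, summing to
#'   `n_patients`.
#' @param sampling_split Counts assigned to sampling groups 1 and 2.
#' @param n_doses Dose after which samples are taken (doses 1..n_doses are
#'   simulated explicitly from drug-free conditions).
#' @param drainage_mean,drainage_sd,drainage_range CSF drainage (mL/day).
#' @param age_mean,age_sd,age_range Age (years).
#' @param weight_mean,weight_sd,weight_range Body weight (kg).
#' @param n_male Number of male patients.
#' @param clcr_mean,clcr_sd,clcr_range Creatinine clearance (mL/min) used
#'   to back-solve serum creatinine.
#' @param time_jitter_sd_min SD (minutes) of optional Gaussian jitter on
#'   nominal sampling times; 0 (default) keeps nominal times.
#' @param missing_frac Fraction of observations dropped completely at
#'   random; 0 by default.
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_patients = 82,
                         regimens = list(`1g q8h` = regimen(1000, 8, 1),
                                         `1g q6h` = regimen(1000, 6, 1),
                                         `2g q8h` = regimen(2000, 8, 2)),
                         regimen_split = c(42, 19, 21),
                         sampling_split = c(40, 42),
                         n_doses = 4,
                         drainage_mean = 126, drainage_sd = 81,
                         drainage_range = c(0, 350),
                         age_mean = 43.4, age_sd = 13.1,
                         age_range = c(19, 77),
                         weight_mean = 65.2, weight_sd = 11.6,
                         weight_range = c(41.5, 100),
                         n_male = 50,
                         clcr_mean = 142.6, clcr_sd = 52.8,
                         clcr_range = c(57.3, 355.7),
                         time_jitter_sd_min = 0,
                         missing_frac = 0) {
  if (sum(regimen_split) != n_patients)
    stop("study_design: 'regimen_split' must sum to 'n_patients'",
         call. = FALSE)
  if (sum(sampling_split) != n_patients)
    stop("study_design: 'sampling_split' must sum to 'n_patients'",
         call. = FALSE)
  if (length(regimens) != length(regimen_split))
    stop("study_design: one split count per regimen required",
         call. = FALSE)
  if (missing_frac < 0 || missing_frac >= 1)
    stop("study_design: 'missing_frac' must be in [0, 1)", call. = FALSE)
  structure(as.list(environment()), class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("Study design: %d patients (%s), samples after dose %d\n",
              x$n_patients,
              paste(sprintf("%d x %s", x$regimen_split, names(x$regimens)),
                    collapse = ", "), x$n_doses))
  invisible(x)
}

# Nominal sampling times relative to the start of the sampled dose.
# Group 1: mid-infusion, end + 10 min, end + 2 h, end + 4 h.
# Group 2: end of infusion, end + 1 h, end + 3 h, pre-next-dose.
.sampling_times <- function(reg, group) {
  D <- reg$infusion_h
  tt <- if (group == 1) c(D / 2, D + 10 / 60, D + 2, D + 4)
  else c(D, D + 1, D + 3, reg$interval_h)
  if (any(tt > reg$interval_h))
    stop("sampling times extend beyond the dosing interval for ",
         regimen_label(reg), call. = FALSE)
  tt
}

.rtnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    y <- rnorm(max(2L * n, 10L), mean, sd)
    out <- c(out, y[y >= lo & y <= hi])
  }
  out[seq_len(n)]
}

#' Cockcroft-Gault creatinine clearance
#'
#' `CLcr = (140 - age) * weight / (72 * SCr)`, multiplied by 0.85 for
#' females; ages above 140 give 0 (boundary).
#'
#' @param age Age (years).
#' @param weight Body weight (kg).
#' @param scr Serum creatinine (mg/dL), `> 0`.
#' @param sex `"M"`/`"F"` (or 1/0); vectorized.
#' @return Creatinine clearance (mL/min).
#' @examples
#' cockcroft_gault(40, 70, 1.0, "M")  # 97.22
#' cockcroft_gault(40, 70, 1.0, "F")  # 82.64
#' @export
cockcroft_gault <- function(age, weight, scr, sex) {
  if (any(!is.finite(scr)) || any(scr <= 0))
    stop("cockcroft_gault: 'scr' must be > 0", call. = FALSE)
  if (any(!is.finite(age)) || any(age < 0) || any(!is.finite(weight)) ||
      any(weight <= 0))
    stop("cockcroft_gault: 'age' and 'weight' must be positive",
         call. = FALSE)
  female <- if (is.character(sex) || is.factor(sex))
    toupper(as.character(sex)) == "F" else sex == 0
  pmax(140 - age, 0) * weight / (72 * scr) * ifelse(female, 0.85, 1)
}

#' Generate a complete synthetic trial dataset
#'
#' Samples individual parameters from the population specification,
#' simulates each patient's first `n_doses` doses explicitly (drug-free
#' start, infusion rate per regimen), evaluates plasma and CSF at the
#' group-specific nominal times around the last dose, and perturbs the
#' observations with the proportional residual error. The true individual
#' parameters are kept in a separate truth table for recovery testing.
#'
#' @param design A [study_design()].
#' @param spec A [pop_spec()].
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return An object of class `study_data`: a list with `data` (pharmaco-
#'   metrics rectangular table: `ID, TIME, AMT, RATE, EVID, CMT, DV, MDV,
#'   DRAIN, AGE, WT, SEX, SCR, CLCR, GRP, REGIMEN`; `CMT` 1 = plasma/central,
#'   2 = CSF; times in hours from first dose), `truth` (per-subject
#'   parameters and covariates) and `design`.
#' @examples
#' ds <- generate_study(study_design(), pop_spec(), seed = 1)
#' nrow(ds$data[ds$data$EVID == 0 & ds$data$CMT == 1, ])  # 328 plasma rows
#' @export
generate_study <- function(design = study_design(), spec = pop_spec(),
                           seed = NULL) {
  stopifnot(inherits(design, "study_design"), inherits(spec, "pop_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- design$n_patients

  cohort <- sample_individuals(spec, n, seed = NULL)
  reg_idx <- rep(seq_along(design$regimens), design$regimen_split)
  grp <- sample(rep(1:2, design$sampling_split))
  drain <- .rtnorm(n, design$drainage_mean, design$drainage_sd,
                   design$drainage_range[1], design$drainage_range[2])
  age <- .rtnorm(n, design$age_mean, design$age_sd,
                 design$age_range[1], design$age_range[2])
  wt <- .rtnorm(n, design$weight_mean, design$weight_sd,
                design$weight_range[1], design$weight_range[2])
  sex <- sample(rep(c("M", "F"), c(design$n_male, n - design$n_male)))
  clcr <- .rtnorm(n, design$clcr_mean, design$clcr_sd,
                  design$clcr_range[1], design$clcr_range[2])
  scr <- pmax(140 - age, 1) * wt * ifelse(sex == "F", 0.85, 1) / (72 * clcr)
  clcr <- cockcroft_gault(age, wt, scr, sex)  # consistent with stored SCr

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    reg <- design$regimens[[reg_idx[i]]]
    tau <- reg$interval_h
    trel <- .sampling_times(reg, grp[i])
    if (design$time_jitter_sd_min > 0) {
      trel <- trel + rnorm(length(trel), 0, design$time_jitter_sd_min / 60)
      trel <- pmin(pmax(trel, 0), tau)
    }
    tobs <- (design$n_doses - 1) * tau + trel
    p <- .cohort_params(cohort, i, drainage_ml_day = drain[i])
    prof <- simulate_doses(p, reg, design$n_doses, tobs)
    dv_pl <- apply_residual_error(prof$conc_plasma, spec$residual_cv)
    dv_cs <- apply_residual_error(prof$conc_csf, spec$residual_cv)
    dose_t <- (seq_len(design$n_doses) - 1) * tau
    sub <- data.frame(
      ID = i,
      TIME = c(dose_t, tobs, tobs),
      AMT = c(rep(reg$dose_mg, design$n_doses), rep(0, 2 * length(tobs))),
      RATE = c(rep(reg$rate_mg_h, design$n_doses),
               rep(0, 2 * length(tobs))),
      EVID = c(rep(1L, design$n_doses), rep(0L, 2 * length(tobs))),
      CMT = c(rep(1L, design$n_doses), rep(1L, length(tobs)),
              rep(2L, length(tobs))),
      DV = c(rep(NA_real_, design$n_doses), dv_pl, dv_cs),
      MDV = c(rep(1L, design$n_doses), rep(0L, 2 * length(tobs))))
    sub$DRAIN <- drain[i]; sub$AGE <- age[i]; sub$WT <- wt[i]
    sub$SEX <- sex[i]; sub$SCR <- scr[i]; sub$CLCR <- clcr[i]
    sub$GRP <- grp[i]; sub$REGIMEN <- names(design$regimens)[reg_idx[i]]
    rows[[i]] <- sub[order(sub$TIME, sub$EVID == 0, sub$CMT), ]
  }
  data <- do.call(rbind, rows)
  if (design$missing_frac > 0) {
    obs <- which(data$EVID == 0)
    drop <- obs[runif(length(obs)) < design$missing_frac]
    if (length(drop)) data <- data[-drop, ]
  }
  rownames(data) <- NULL

  truth <- cbind(cohort,
                 data.frame(drainage_ml_day = drain, age = age, weight = wt,
                            sex = sex, scr = scr, clcr = clcr,
                            regimen = names(design$regimens)[reg_idx],
                            sampling_group = grp))
  structure(list(data = data, truth = truth, design = design, spec = spec,
                 seed = seed),
            class = "study_data")
}

#' @export
print.study_data <- function(x, ...) {
  obs <- x$data[x$data$EVID == 0, ]
  cat(sprintf(paste0("Synthetic study dataset: %d subjects, %d plasma + %d",
                     " CSF observations\n"),
              length(unique(x$data$ID)), sum(obs$CMT == 1),
              sum(obs$CMT == 2)))
  invisible(x)
}

#' Write / read a study dataset in the rectangular CSV dialect
#'
#' `write_study()` writes `<stem>.csv` (observable table) and
#' `<stem>_truth.csv` (true individual parameters). `read_study()` reads
#' the observable table back (truth table read when present).
#'
#' @param ds A `study_data` object.
#' @param stem Output path stem (no extension).
#' @param path Path to a dataset CSV written by `write_study()`.
#' @export
write_study <- function(ds, stem) {
  stopifnot(inherits(ds, "study_data"))
  write.csv(ds$data, paste0(stem, ".csv"), row.names = FALSE, na = ".")
  write.csv(ds$truth, paste0(stem, "_truth.csv"), row.names = FALSE)
  invisible(paste0(stem, c(".csv", "_truth.csv")))
}

#' @rdname write_study
#' @export
read_study <- function(path) {
  data <- read.csv(path, na.strings = ".")
  truth_path <- sub("\\.csv$", "_truth.csv", path)
  truth <- if (file.exists(truth_path)) read.csv(truth_path) else NULL
  structure(list(data = data, truth = truth, design = NULL, spec = NULL,
                 seed = NULL),
            class = "study_data")
}
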