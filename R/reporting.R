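# Workflow entry points binding the modules together: the full-factorial
# PTA simulation with breakpoint tables and a machine-readable
# recommendation, and an end-to-end demonstration run
# (generate -> fit -> vpc -> simulate-pta). Every output file embeds the
# package version, a config checksum and the seed; existing files are
# never overwritten silently.

# Small rolling checksum of a deparsed configuration (the environment has
# no hashing package; this is a provenance marker, not a cryptographic
# hash).
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.out_header <- function(config, seed) {
  c(sprintf("meropk %s", as.character(packageVersion("meropk"))),
    sprintf("config_hash %s", .config_hash(config)),
    sprintf("seed %s", paste(seed, collapse = ",")))
}

.check_overwrite <- function(paths, force) {
  ex <- paths[file.exists(paths)]
  if (length(ex) && !force)
    stop("output exists (use force = TRUE to overwrite): ",
         paste(ex, collapse = ", "), call. = FALSE)
}

.stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("[%s] stage failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  message(sprintf("[%s] done in %.1f s", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Full-factorial PTA simulation with breakpoints and recommendation
#'
#' Crosses the candidate regimens (1 g q8h, 1 g q6h, 2 g q8h) with
#' infusion durations (0.5, 1, 2, 3, 4 h and continuous) and CSF drainage
#' rates (0, 50, 150, 250 mL/day) over the MIC dilution series, evaluates
#' all three fT>MIC targets on a shared virtual cohort, and writes the PTA
#' table, breakpoint tables at PTA floors 0.90 and 0.80, a PTA figure and
#' a machine-readable recommendation: the non-continuous regimen/infusion
#' maximizing the CSF breakpoints at floor 0.90 under limited drainage.
#'
#' @param out_dir Output directory (created if needed).
#' @param spec A [pop_spec()].
#' @param regimens,infusion_h,drainage_ml_day,targets,mics,n_grid Passed
#'   to [pta_grid()].
#' @param n Virtual cohort size.
#' @param seed Integer seed.
#' @param force Overwrite existing outputs.
#' @param plot Also write a `pta_plot.pdf` figure.
#' @return Invisibly, a list with `grid`, `breakpoints` and
#'   `recommendation`.
#' @export
run_simulate_pta <- function(out_dir, spec = pop_spec(),
                             regimens = list(`1g q8h` = regimen(1000, 8),
                                             `1g q6h` = regimen(1000, 6),
                                             `2g q8h` = regimen(2000, 8)),
                             infusion_h = c(0.5, 1, 2, 3, 4, Inf),
                             drainage_ml_day = c(0, 50, 150, 250),
                             targets = default_targets(),
                             mics = 2^seq(-5, 6),
                             n = 1000, seed = 1, n_grid = 1000,
                             force = FALSE, plot = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("pta.csv", "breakpoints.csv",
                                "recommendation.json", "pta_plot.pdf"))
  .check_overwrite(paths[c(1:3, if (plot) 4)], force)
  config <- list(regimens = lapply(regimens, unclass),
                 infusion_h = infusion_h,
                 drainage_ml_day = drainage_ml_day, mics = mics, n = n,
                 n_grid = n_grid)
  hdr <- .out_header(config, seed)

  grid <- .stage("simulate-pta",
                 pta_grid(spec, regimens = regimens,
                          infusion_h = infusion_h,
                          drainage_ml_day = drainage_ml_day,
                          targets = targets, mics = mics, n = n,
                          seed = seed, n_grid = n_grid))
  bp <- rbind(pkpd_breakpoint(grid, 0.90), pkpd_breakpoint(grid, 0.80))
  rec <- recommend_regimen(grid, pta_floor = 0.90,
                           max_drainage_ml_day = 150)
  write_pta(grid, paths[1], header = hdr)
  con <- file(paths[2], "w")
  writeLines(paste0("# ", hdr), con)
  write.csv(bp, con, row.names = FALSE)
  close(con)
  jsonlite::write_json(
    c(list(package_version = as.character(packageVersion("meropk")),
           config_hash = .config_hash(config), seed = seed), rec),
    paths[3], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (plot) {
    pdf(paths[4], width = 7, height = 9)
    plot(grid)
    dev.off()
  }
  invisible(list(grid = grid, breakpoints = bp, recommendation = rec))
}

#' Pick the recommended regimen from a PTA grid
#'
#' Among non-continuous scenarios with drainage at most
#' `max_drainage_ml_day`, selects the (regimen, infusion duration) whose
#' worst-case-over-drainage CSF breakpoints at `pta_floor` are maximal
#' (50% target first, then 100% target, then the plasma breakpoint as
#' tie-breaks, then the shorter infusion).
#'
#' @param grid A `pta_grid`.
#' @param pta_floor PTA floor for breakpoints.
#' @param max_drainage_ml_day Drainage cap defining "limited drainage".
#' @return A list describing the recommended scenario and its breakpoints.
#' @export
recommend_regimen <- function(grid, pta_floor = 0.90,
                              max_drainage_ml_day = 150) {
  bp <- pkpd_breakpoint(grid, pta_floor)
  bp <- bp[is.finite(bp$infusion_h) &
             bp$drainage_ml_day <= max_drainage_ml_day, ]
  key <- unique(bp[c("regimen", "infusion_h")])
  score <- function(reg, D, matrix, frac) {
    v <- bp$breakpoint_mg_l[bp$regimen == reg & bp$infusion_h == D &
                              bp$matrix == matrix &
                              bp$target_fraction == frac]
    if (!length(v) || all(is.na(v))) return(0)
    min(v, na.rm = TRUE)  # worst case over allowed drainage rates
  }
  key$csf50 <- mapply(score, key$regimen, key$infusion_h, "csf", 0.50)
  key$csf100 <- mapply(score, key$regimen, key$infusion_h, "csf", 1.00)
  key$plasma40 <- mapply(score, key$regimen, key$infusion_h, "plasma",
                         0.40)
  key <- key[order(-key$csf50, -key$csf100, -key$plasma40,
                   key$infusion_h), ]
  best <- key[1, ]
  list(recommended_regimen = best$regimen,
       infusion_h = best$infusion_h,
       drainage_cap_ml_day = max_drainage_ml_day,
       pta_floor = pta_floor,
       csf_breakpoint_50_mg_l = best$csf50,
       csf_breakpoint_100_mg_l = best$csf100,
       plasma_breakpoint_40_mg_l = best$plasma40)
}

#' End-to-end demonstration run
#'
#' Exercises every module at reduced scale: generates a synthetic study,
#' fits it, runs a visual predictive check, and evaluates a reduced PTA
#' factorial; writes `study.csv`, `study_truth.csv`, `fit.json`,
#' `vpc.csv`, `pta.csv`, `breakpoints.csv` and `recommendation.json` to
#' `out_dir`. All artifacts are byte-reproducible for a fixed seed.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param n_pta Virtual cohort size for the PTA stage.
#' @param n_boot Bootstrap replicates for the fit uncertainty.
#' @param n_sim VPC replicate datasets.
#' @param design,spec Study design and generating population.
#' @param force Overwrite existing outputs.
#' @return Invisibly, a list with the stage results.
#' @export
run_demo <- function(out_dir, seed = 1, n_pta = 200, n_boot = 50,
                     n_sim = 100, design = study_design(),
                     spec = pop_spec(), force = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(out_dir, c("study.csv", "study_truth.csv",
                                "fit.json", "vpc.csv"))
  .check_overwrite(files, force)
  config <- list(n_pta = n_pta, n_boot = n_boot, n_sim = n_sim)
  hdr <- .out_header(config, seed)

  ds <- .stage("generate", generate_study(design, spec, seed = seed))
  write_study(ds, file.path(out_dir, "study"))

  fit <- .stage("fit", pk_fit(ds, init = spec$typical,
                              start_scales = c(1, 2)))
  boot <- .stage("bootstrap",
                 bootstrap_ci(fit, n_boot = n_boot, seed = seed + 1))
  write_fit(fit, file.path(out_dir, "fit.json"),
            extra = list(config_hash = .config_hash(config), seed = seed,
                         bootstrap = list(n_boot = n_boot,
                                          n_failed = attr(boot, "n_failed"),
                                          intervals = boot)))

  v <- .stage("vpc", vpc(ds, spec, n_sim = n_sim, seed = seed + 2))
  write_vpc(v, file.path(out_dir, "vpc.csv"), header = hdr)

  ptares <- .stage("simulate-pta",
                   run_simulate_pta(out_dir, spec = spec,
                                    infusion_h = c(0.5, 4, Inf),
                                    n = n_pta, seed = seed + 3,
                                    force = force, plot = FALSE))
  invisible(list(study = ds, fit = fit, bootstrap = boot, vpc = v,
                 pta = ptares))
}
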