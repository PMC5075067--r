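# Structural parameter sets, dosing regimens and population specifications,
# plus their config-file (YAML/JSON) round trips.

#' Structural pharmacokinetic parameter set
#'
#' Builds and validates the parameter set of the three-compartment
#' plasma-CSF model. Defaults are the published typical values for
#' postneurosurgical meningitis patients. Elimination from the CSF
#' compartment is not estimated but computed from the daily CSF drainage
#' volume: under the default reading the drainage flow is a clearance,
#' `CL2 = drainage (L/day) / 24` (L/h), so `k20 = CL2 / V2` (1/h). Setting
#' `drainage_as_rate_constant = TRUE` selects the literal alternative in
#' which `k20 = drainage (L/day) / 24` is itself a rate constant (1/h), so
#' `CL2 = k20 * V2`.
#'
#' @param v1 Central compartment volume (L).
#' @param v2 CSF compartment volume (L).
#' @param v3 Peripheral compartment volume (L).
#' @param cl1 Central (elimination) clearance (L/h).
#' @param q1 Central-CSF intercompartmental clearance (L/h).
#' @param q2 Central-peripheral intercompartmental clearance (L/h).
#' @param pc Dimensionless transfer multiplier applied to the central-to-CSF
#'   flux (the CSF penetration factor).
#' @param drainage_ml_day Daily CSF drainage volume (mL/day), `>= 0`.
#' @param drainage_as_rate_constant Interpret the drainage flow as a rate
#'   constant rather than a clearance (see Details).
#' @return An object of class `pk_params` (a named list).
#' @examples
#' p <- pk_params()                 # published typical values
#' csf_clearance(p)                 # 0 L/h without drainage
#' csf_clearance(pk_params(drainage_ml_day = 126))
#' @export
pk_params <- function(v1 = 17.9, v2 = 0.13, v3 = 3.84,
                      cl1 = 22.2, q1 = 0.010, q2 = 1.79, pc = 0.172,
                      drainage_ml_day = 0,
                      drainage_as_rate_constant = FALSE) {
  p <- structure(list(v1 = v1, v2 = v2, v3 = v3, cl1 = cl1, q1 = q1,
                      q2 = q2, pc = pc, drainage_ml_day = drainage_ml_day,
                      drainage_as_rate_constant =
                        isTRUE(drainage_as_rate_constant)),
                 class = "pk_params")
  validate_pk_params(p)
}

#' @rdname pk_params
#' @param p A `pk_params` object.
#' @export
validate_pk_params <- function(p) {
  strict_pos <- c("v1", "v2", "v3", "q1", "q2", "pc")
  for (nm in strict_pos) {
    val <- p[[nm]]
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val <= 0)
      stop("pk_params: field '", nm, "' must be a single strictly positive ",
           "finite number (got ", format(val), ")", call. = FALSE)
  }
  # cl1 = 0 (closed system) is allowed for simulation; it admits no
  # periodic steady state, which steady_state_amounts() reports.
  for (nm in c("cl1", "drainage_ml_day")) {
    val <- p[[nm]]
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val < 0)
      stop("pk_params: field '", nm, "' must be a single finite number ",
           ">= 0 (got ", format(val), ")", call. = FALSE)
  }
  p
}

#' CSF-compartment clearance implied by the drainage rate
#'
#' @param p A [pk_params()] object.
#' @return Clearance of the CSF compartment, `CL2` (L/h).
#' @export
csf_clearance <- function(p) {
  flow <- (p$drainage_ml_day / 1000) / 24   # L/day -> L/h
  if (p$drainage_as_rate_constant) flow * p$v2 else flow
}

#' @export
print.pk_params <- function(x, ...) {
  cat("Three-compartment plasma-CSF PK parameters\n")
  cat(sprintf("  V1 %6.3g L   V2 %6.3g L   V3 %6.3g L\n", x$v1, x$v2, x$v3))
  cat(sprintf("  CL1 %5.3g L/h  Q1 %6.3g L/h  Q2 %5.3g L/h  PC %6.3g\n",
              x$cl1, x$q1, x$q2, x$pc))
  cat(sprintf("  CSF drainage %g mL/day -> CL2 %.4g L/h (%s reading)\n",
              x$drainage_ml_day, csf_clearance(x),
              if (x$drainage_as_rate_constant) "rate-constant" else
                "clearance"))
  invisible(x)
}

#' Dosing regimen
#'
#' An intermittent- or continuous-infusion regimen. With
#' `continuous = TRUE` the regimen delivers the same total daily dose at a
#' constant rate (e.g. 2 g q8h as continuous infusion is 250 mg/h), which is
#' represented internally as an infusion lasting the whole interval.
#'
#' @param dose_mg Dose per administration (mg), `>= 0` (0 gives the null
#'   regimen, useful as a control).
#' @param interval_h Dosing interval tau (h), `> 0`.
#' @param infusion_h Infusion duration (h), `0 < infusion_h <= interval_h`.
#'   Ignored when `continuous = TRUE`.
#' @param continuous Give the daily dose at constant rate.
#' @return An object of class `pk_regimen`.
#' @examples
#' regimen(2000, 8, 4)             # 2 g q8h, 4-h infusion
#' regimen(2000, 8, continuous = TRUE)  # 250 mg/h continuous infusion
#' @export
regimen <- function(dose_mg, interval_h, infusion_h = 1,
                    continuous = FALSE) {
  if (!is.numeric(dose_mg) || length(dose_mg) != 1L || !is.finite(dose_mg) ||
      dose_mg < 0)
    stop("regimen: 'dose_mg' must be a single number >= 0", call. = FALSE)
  if (!is.numeric(interval_h) || length(interval_h) != 1L ||
      !is.finite(interval_h) || interval_h <= 0)
    stop("regimen: 'interval_h' must be a single number > 0", call. = FALSE)
  if (continuous) infusion_h <- interval_h
  if (!is.numeric(infusion_h) || length(infusion_h) != 1L ||
      !is.finite(infusion_h) || infusion_h <= 0 || infusion_h > interval_h)
    stop("regimen: 'infusion_h' must satisfy 0 < infusion_h <= interval_h",
         call. = FALSE)
  structure(list(dose_mg = dose_mg, interval_h = interval_h,
                 infusion_h = infusion_h, continuous = isTRUE(continuous),
                 rate_mg_h = if (dose_mg > 0) dose_mg / infusion_h else 0),
            class = "pk_regimen")
}

#' @export
print.pk_regimen <- function(x, ...) {
  cat(regimen_label(x), "\n")
  invisible(x)
}

#' Human-readable regimen label, e.g. "2 g q8h, 4-h infusion"
#' @param reg A [regimen()] object.
#' @export
regimen_label <- function(reg) {
  dose <- if (reg$dose_mg %% 1000 == 0) paste0(reg$dose_mg / 1000, " g") else
    paste0(reg$dose_mg, " mg")
  inf <- if (reg$continuous) "continuous infusion" else
    paste0(format(reg$infusion_h), "-h infusion")
  sprintf("%s q%gh, %s", dose, reg$interval_h, inf)
}

#' Population specification: typical values, BSV and residual error
#'
#' Couples the typical structural parameters with the between-subject
#' variability (BSV, as CV%) and the proportional residual error (CV%).
#' Defaults are the published estimates: BSV on V1 (13.2%), V2 (37.4%),
#' CL1 (22.4%), Q1 (84.4%) and PC (39.4%); V3 and Q2 carry no BSV;
#' residual proportional error 34.9%. BSV is log-normal:
#' `P_i = TV * exp(eta)`, `eta ~ N(0, log(1 + (CV/100)^2))`.
#'
#' @param typical A [pk_params()] object of typical values.
#' @param bsv_cv Named numeric vector of CV% values; names among
#'   `v1, v2, v3, cl1, q1, q2, pc`. Parameters not named are fixed.
#' @param residual_cv Proportional residual error CV%.
#' @return An object of class `pop_spec`.
#' @export
pop_spec <- function(typical = pk_params(),
                     bsv_cv = c(v1 = 13.2, v2 = 37.4, cl1 = 22.4,
                                q1 = 84.4, pc = 39.4),
                     residual_cv = 34.9) {
  typical <- validate_pk_params(typical)
  if (length(bsv_cv)) {
    if (is.null(names(bsv_cv)) ||
        !all(names(bsv_cv) %in% c("v1", "v2", "v3", "cl1", "q1", "q2", "pc")))
      stop("pop_spec: 'bsv_cv' must be named with structural parameter names",
           call. = FALSE)
    if (any(!is.finite(bsv_cv)) || any(bsv_cv < 0))
      stop("pop_spec: BSV CV% values must be finite and >= 0", call. = FALSE)
  }
  if (!is.numeric(residual_cv) || length(residual_cv) != 1L ||
      !is.finite(residual_cv) || residual_cv < 0)
    stop("pop_spec: 'residual_cv' must be a single number >= 0",
         call. = FALSE)
  structure(list(typical = typical, bsv_cv = bsv_cv,
                 residual_cv = residual_cv),
            class = "pop_spec")
}

#' @export
print.pop_spec <- function(x, ...) {
  cat("Population PK specification\n")
  print(x$typical)
  if (length(x$bsv_cv))
    cat("  BSV CV%: ",
        paste(sprintf("%s %.3g", names(x$bsv_cv), x$bsv_cv),
              collapse = ", "), "\n", sep = "")
  cat(sprintf("  Proportional residual error: %.3g%%\n", x$residual_cv))
  invisible(x)
}

# ---- config round trips -----------------------------------------------

.params_to_config <- function(p) {
  list(v1_l = p$v1, v2_l = p$v2, v3_l = p$v3,
       cl1_l_per_h = p$cl1, q1_l_per_h = p$q1, q2_l_per_h = p$q2,
       pc = p$pc, drainage_ml_day = p$drainage_ml_day,
       drainage_as_rate_constant = p$drainage_as_rate_constant)
}

.params_from_config <- function(x) {
  pk_params(v1 = x$v1_l, v2 = x$v2_l, v3 = x$v3_l, cl1 = x$cl1_l_per_h,
            q1 = x$q1_l_per_h, q2 = x$q2_l_per_h, pc = x$pc,
            drainage_ml_day = x$drainage_ml_day %||% 0,
            drainage_as_rate_constant =
              isTRUE(x$drainage_as_rate_constant))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_config <- function(x, path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(x, path)
  else
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(path)
}

.read_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Read and write parameter / population configs
#'
#' Parameter sets and population specifications round-trip through YAML or
#' JSON files (chosen by extension) with unit-suffixed field names
#' (`cl1_l_per_h`, `drainage_ml_day`, ...).
#'
#' @param p,spec Objects to serialize.
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return The read functions return a [pk_params()] / [pop_spec()] object;
#'   the write functions return `path` invisibly.
#' @export
write_params_config <- function(p, path) {
  .write_config(.params_to_config(validate_pk_params(p)), path)
}

#' @rdname write_params_config
#' @export
read_params_config <- function(path) .params_from_config(.read_config(path))

#' @rdname write_params_config
#' @export
write_pop_spec_config <- function(spec, path) {
  stopifnot(inherits(spec, "pop_spec"))
  .write_config(list(typical = .params_to_config(spec$typical),
                     bsv_cv_percent = as.list(spec$bsv_cv),
                     residual_cv_percent = spec$residual_cv), path)
}

#' @rdname write_params_config
#' @export
read_pop_spec_config <- function(path) {
  x <- .read_config(path)
  pop_spec(typical = .params_from_config(x$typical),
           bsv_cv = unlist(x$bsv_cv_percent),
           residual_cv = x$residual_cv_percent)
}
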