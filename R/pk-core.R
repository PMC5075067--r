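# Deterministic simulation of the three-compartment plasma-CSF system.
#
# State x = (A1 central, A2 CSF, A3 peripheral) in mg; dx/dt = A x + b(t)
# with b the infusion input into the central compartment. The system is
# linear with piecewise-constant input, so it is propagated exactly per
# infusion-on / infusion-off segment via the matrix exponential
# (eigendecomposition fast path; Pade via Matrix::expm on an augmented
# matrix when A is singular or defective, as with all clearances zero).

#' Rate matrix of the plasma-CSF model
#'
#' Assembles the 3x3 linear-system matrix for drug amounts
#' (central, CSF, peripheral). The central-to-CSF flux uses clearance
#' `Q1 * PC` while the CSF-to-central return uses `Q1` (asymmetric by
#' construction: `K12 = Q1*PC/V1`, `K21 = Q1/V2`); CSF elimination is
#' `k20 = CL2/V2` with `CL2` derived from the drainage rate
#' (see [csf_clearance()]).
#'
#' @param params A [pk_params()] object.
#' @return A 3x3 numeric matrix with units 1/h; all eigenvalues have
#'   strictly negative real part whenever `cl1 > 0`.
#' @examples
#' A <- pk_system_matrix(pk_params())
#' -A[1, 1]  # k10 + k12 + Q2/V1
#' @export
pk_system_matrix <- function(params) {
  p <- validate_pk_params(params)
  cl2 <- csf_clearance(p)
  matrix(c(
    -(p$cl1 + p$q2 + p$q1 * p$pc) / p$v1,  p$q1 / p$v2,            p$q2 / p$v3,
     (p$q1 * p$pc) / p$v1,                -(p$q1 + cl2) / p$v2,    0,
     p$q2 / p$v1,                          0,                     -p$q2 / p$v3),
    nrow = 3, byrow = TRUE)
}

# Eigendecomposition cache: NULL when A is not (numerically) diagonalizable.
.pk_eig <- function(A) {
  e <- eigen(A)
  P <- e$vectors
  Pinv <- tryCatch(solve(P), error = function(err) NULL)
  if (is.null(Pinv)) return(NULL)
  # reject near-defective decompositions
  if (max(Mod(P %*% (e$values * Pinv) - A)) > 1e-8 * max(1, max(Mod(A))))
    return(NULL)
  list(P = P, Pinv = Pinv, lam = e$values,
       invertible = min(Mod(e$values)) > 1e-12 * max(Mod(e$values), 1))
}

# x(t) for t in tvec (relative to segment start), dx/dt = A x + (rate,0,0),
# x(0) = x0. Returns a 3 x length(tvec) matrix of amounts.
.prop_eig <- function(A, eig, x0, rate, tvec) {
  xinf <- if (rate == 0) c(0, 0, 0) else solve(A, -c(rate, 0, 0))
  u <- as.vector(eig$Pinv %*% (x0 - xinf))
  amt <- Re(eig$P %*% (exp(outer(eig$lam, tvec)) * u))
  amt + xinf
}

# Slow exact fallback: augmented 4x4 exponential handles singular/defective A.
.prop_expm <- function(A, x0, rate, tvec) {
  M <- rbind(cbind(A, c(rate, 0, 0)), 0)
  z <- c(x0, 1)
  vapply(tvec, function(t) {
    (as.matrix(Matrix::expm(M * t)) %*% z)[1:3, 1]
  }, numeric(3))
}

.propagate <- function(A, x0, rate, tvec, eig = NULL) {
  if (is.null(eig)) eig <- .pk_eig(A)
  if (!is.null(eig) && (rate == 0 || eig$invertible))
    .prop_eig(A, eig, x0, rate, tvec)
  else
    .prop_expm(A, x0, rate, tvec)
}

# Generic piecewise-constant-input simulation over ordered segments.
# segs: data.frame(a, b, rate); times: absolute times, all >= 0.
# Returns 3 x length(times) amounts; x0 is the state at segs$a[1].
.sim_piecewise <- function(A, eig, segs, times, x0 = c(0, 0, 0)) {
  out <- matrix(0, 3, length(times))
  x <- x0
  for (i in seq_len(nrow(segs))) {
    a <- segs$a[i]; b <- segs$b[i]
    idx <- which(times > a & times <= b)
    tt <- c(times[idx] - a, b - a)
    res <- .propagate(A, x, segs$rate[i], tt, eig)
    if (length(idx)) out[, idx] <- res[, seq_along(idx), drop = FALSE]
    x <- res[, length(tt)]
  }
  i0 <- which(times <= segs$a[1])
  if (length(i0)) out[, i0] <- x0
  out
}

# Segment table for n identical doses of a regimen starting at t = 0,
# extended with a terminal washout up to tmax.
.regimen_segments <- function(reg, n_doses, tmax) {
  starts <- (seq_len(n_doses) - 1) * reg$interval_h
  a <- as.vector(rbind(starts, starts + reg$infusion_h))
  rate <- as.vector(rbind(rep(reg$rate_mg_h, n_doses), rep(0, n_doses)))
  b <- c(a[-1], max(tmax, n_doses * reg$interval_h))
  keep <- b > a
  data.frame(a = a[keep], b = b[keep], rate = rate[keep])
}

#' Simulate repeated dosing from drug-free initial conditions
#'
#' Explicit (transient, not steady-state) simulation of `n_doses`
#' identical administrations of a regimen, evaluated at arbitrary absolute
#' times from the start of the first infusion.
#'
#' @param params A [pk_params()] object.
#' @param reg A [regimen()] object.
#' @param n_doses Number of doses administered.
#' @param times Numeric vector of absolute times (h), `>= 0`; may extend
#'   beyond the last dosing interval (terminal washout).
#' @return A `conc_profile` object (see [conc_profile()]).
#' @export
simulate_doses <- function(params, reg, n_doses, times) {
  params <- validate_pk_params(params)
  stopifnot(inherits(reg, "pk_regimen"), n_doses >= 1,
            is.numeric(times), all(is.finite(times)), all(times >= 0))
  A <- pk_system_matrix(params)
  segs <- .regimen_segments(reg, n_doses, max(times))
  amt <- .sim_piecewise(A, .pk_eig(A), segs, times)
  .profile_from_amounts(times, amt, params, reg)
}

#' Amounts at the periodic steady state
#'
#' Solves for the fixed point of the interval map: amounts `x*` at the
#' start of a dosing interval such that simulating one full interval
#' (infusion on, then off) returns `x*`. Solved as the linear system
#' `(I - Phi(tau)) x* = g(tau)` where `Phi` is the interval propagator and
#' `g` the response to one dose from the drug-free state.
#'
#' @inheritParams simulate_doses
#' @return Numeric vector of length 3: amounts (mg) in central, CSF and
#'   peripheral compartments at the moment of dose administration.
#' @export
steady_state_amounts <- function(params, reg) {
  params <- validate_pk_params(params)
  stopifnot(inherits(reg, "pk_regimen"))
  if (reg$dose_mg == 0) return(c(0, 0, 0))
  A <- pk_system_matrix(params)
  eig <- .pk_eig(A)
  tau <- reg$interval_h; D <- reg$infusion_h
  xD <- .propagate(A, c(0, 0, 0), reg$rate_mg_h, D, eig)[, 1]
  g <- if (D < tau) .propagate(A, xD, 0, tau - D, eig)[, 1] else xD
  Phi <- if (!is.null(eig))
    Re(eig$P %*% (exp(eig$lam * tau) * eig$Pinv))
  else
    as.matrix(Matrix::expm(A * tau))
  xstar <- tryCatch(solve(diag(3) - Phi, g), error = function(err)
    stop("steady_state_amounts: (I - Phi) is singular; the system has no ",
         "periodic steady state (is cl1 zero?)", call. = FALSE))
  pmax(xstar, 0)  # clip tiny negative round-off
}

# Shared worker: steady-state amounts evaluated on a time grid in [0, tau].
.ss_amounts_on_grid <- function(A, eig, reg, xstar, times) {
  D <- reg$infusion_h
  segs <- data.frame(a = c(0, D), b = c(D, reg$interval_h),
                     rate = c(reg$rate_mg_h, 0))
  segs <- segs[segs$b > segs$a, , drop = FALSE]
  amt <- .sim_piecewise(A, eig, segs, times, x0 = xstar)
  amt[, times == 0] <- xstar
  amt
}

#' Steady-state concentration profile over one dosing interval
#'
#' `steady_state_profile()` evaluates the periodic steady state on a time
#' grid spanning one dosing interval; `simulate_profile()` is the same
#' computation restricted to a user grid within `[0, tau]` (times measured
#' from the start of an infusion at steady state).
#'
#' @inheritParams simulate_doses
#' @param times Time grid within `[0, interval_h]`; default
#'   `n_grid + 1` evenly spaced points including both endpoints.
#' @param n_grid Number of grid subdivisions when `times` is `NULL`.
#' @return A [conc_profile()] object.
#' @examples
#' prof <- steady_state_profile(pk_params(drainage_ml_day = 50),
#'                              regimen(2000, 8, 4))
#' max(prof$conc_plasma)
#' @export
steady_state_profile <- function(params, reg, times = NULL, n_grid = 1000) {
  params <- validate_pk_params(params)
  stopifnot(inherits(reg, "pk_regimen"))
  if (is.null(times))
    times <- seq(0, reg$interval_h, length.out = n_grid + 1)
  if (any(times < 0) || any(times > reg$interval_h))
    stop("steady_state_profile: 'times' must lie within [0, interval_h]",
         call. = FALSE)
  if (reg$dose_mg == 0)
    return(.profile_from_amounts(times, matrix(0, 3, length(times)),
                                 params, reg))
  A <- pk_system_matrix(params)
  eig <- .pk_eig(A)
  xstar <- steady_state_amounts(params, reg)
  amt <- .ss_amounts_on_grid(A, eig, reg, xstar, times)
  .profile_from_amounts(times, amt, params, reg)
}

#' @rdname steady_state_profile
#' @export
simulate_profile <- function(params, reg, times = NULL, n_grid = 1000)
  steady_state_profile(params, reg, times = times, n_grid = n_grid)

# ---- concentration profiles -------------------------------------------

.profile_from_amounts <- function(times, amt, params, reg) {
  amt <- pmax(amt, 0)
  conc_profile(times,
               conc_plasma = amt[1, ] / params$v1,
               conc_csf = amt[2, ] / params$v2,
               amounts = t(amt), params = params, regimen = reg)
}

#' Concentration-time profile container
#'
#' Holds one individual's plasma and CSF concentration curves on a common
#' time grid, with the underlying per-compartment amounts when available.
#'
#' @param times Time grid (h).
#' @param conc_plasma,conc_csf Total concentrations (mg/L), same length as
#'   `times`, all `>= 0`.
#' @param amounts Optional `length(times) x 3` matrix of compartment
#'   amounts (mg).
#' @param params,regimen Optional provenance ([pk_params()], [regimen()]).
#' @return An object of class `conc_profile`.
#' @export
conc_profile <- function(times, conc_plasma, conc_csf, amounts = NULL,
                         params = NULL, regimen = NULL) {
  stopifnot(length(conc_plasma) == length(times),
            length(conc_csf) == length(times))
  if (any(conc_plasma < 0) || any(conc_csf < 0))
    stop("conc_profile: concentrations must be >= 0", call. = FALSE)
  structure(list(times = as.numeric(times),
                 conc_plasma = as.numeric(conc_plasma),
                 conc_csf = as.numeric(conc_csf),
                 amounts = amounts, params = params, regimen = regimen),
            class = "conc_profile")
}

#' @export
print.conc_profile <- function(x, ...) {
  cat(sprintf("Concentration profile: %d points over [%g, %g] h\n",
              length(x$times), min(x$times), max(x$times)))
  cat(sprintf("  plasma Cmax %.4g, Cmin %.4g mg/L; CSF Cmax %.4g, Cmin %.4g mg/L\n",
              max(x$conc_plasma), min(x$conc_plasma),
              max(x$conc_csf), min(x$conc_csf)))
  invisible(x)
}

#' @export
as.data.frame.conc_profile <- function(x, ...) {
  data.frame(time_h = x$times, conc_plasma_mg_l = x$conc_plasma,
             conc_csf_mg_l = x$conc_csf)
}

#' @export
plot.conc_profile <- function(x, log = "", ...) {
  df <- as.data.frame(x)
  matlines_y <- cbind(df$conc_plasma_mg_l, df$conc_csf_mg_l)
  plot(range(df$time_h), range(matlines_y[matlines_y > 0 | log == ""]),
       type = "n", xlab = "Time (h)", ylab = "Concentration (mg/L)",
       log = log, ...)
  lines(df$time_h, df$conc_plasma_mg_l, col = "black")
  lines(df$time_h, df$conc_csf_mg_l, col = "firebrick")
  legend("topright", c("plasma", "CSF"), col = c("black", "firebrick"),
         lty = 1, bty = "n")
  invisible(x)
}

#' Export a profile as tidy CSV
#' @param profile A [conc_profile()] object.
#' @param path Output CSV path.
#' @export
write_profile <- function(profile, path) {
  write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' Trapezoidal AUC over the profile grid
#' @param profile A [conc_profile()] object.
#' @param matrix `"plasma"` or `"csf"`.
#' @return AUC in mg*h/L.
#' @export
profile_auc <- function(profile, matrix = c("plasma", "csf")) {
  matrix <- match.arg(matrix)
  y <- if (matrix == "plasma") profile$conc_plasma else profile$conc_csf
  t <- profile$times
  sum(diff(t) * (head(y, -1) + y[-1]) / 2)
}
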