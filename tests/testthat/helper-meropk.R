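# Shared fixtures: everything is generated in code at test time.

# Published typical values with a drainage rate attached.
tbl_params <- function(drainage_ml_day = 0, ...)
  pk_params(drainage_ml_day = drainage_ml_day, ...)

# Random valid parameter set, log-uniform around the typical values.
rand_params <- function(drainage_ml_day = stats::runif(1, 0, 350)) {
  r <- function(x, w = 1.2) x * exp(stats::runif(1, -w, w))
  pk_params(v1 = r(17.9), v2 = r(0.13), v3 = r(3.84), cl1 = r(22.2),
            q1 = r(0.010), q2 = r(1.79), pc = r(0.172),
            drainage_ml_day = drainage_ml_day)
}

# Independent ODE oracle: adaptive integration (deSolve::lsoda) of the
# piecewise-constant-input system, per infusion/washout segment.
ode_oracle <- function(params, reg, n_doses, times) {
  A <- pk_system_matrix(params)
  segs <- meropk:::.regimen_segments(reg, n_doses, max(times))
  deriv <- function(t, y, parms) list(A %*% y + c(parms$rate, 0, 0))
  x <- c(0, 0, 0)
  out <- matrix(NA_real_, 3, length(times))
  for (i in seq_len(nrow(segs))) {
    tt <- sort(unique(c(0, times[times > segs$a[i] & times <= segs$b[i]] -
                          segs$a[i], segs$b[i] - segs$a[i])))
    sol <- deSolve::lsoda(x, tt, deriv, parms = list(rate = segs$rate[i]),
                          rtol = 1e-10, atol = 1e-12)
    for (t in times[times > segs$a[i] & times <= segs$b[i]])
      out[, which(times == t)] <- sol[abs(sol[, 1] - (t - segs$a[i])) <
                                        1e-12, 2:4]
    x <- sol[nrow(sol), 2:4]
  }
  out[, times == 0] <- 0
  out
}

# Small study design for fast estimation tests.
small_design <- function(n = 12)
  study_design(n_patients = n,
               regimen_split = c(n - 2 * floor(n / 4), floor(n / 4),
                                 floor(n / 4)),
               sampling_split = c(floor(n / 2), n - floor(n / 2)),
               n_male = floor(n / 2))
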