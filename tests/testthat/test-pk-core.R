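# The rate matrix and the exact (matrix-exponential) simulation of the
# three-compartment plasma-CSF system.

test_that("rate constants derived from the typical values are exact", {
  A <- pk_system_matrix(tbl_params())
  expect_equal(A[2, 1], 0.010 * 0.172 / 17.9)        # K12 = Q1*PC/V1
  expect_equal(A[1, 2], 0.010 / 0.13)                # K21 = Q1/V2
  # k10 = CL1/V1 recovered from the diagonal after removing Q2 and K12
  expect_equal(-A[1, 1] - 1.79 / 17.9 - A[2, 1], 22.2 / 17.9,
               tolerance = 1e-12)
  expect_equal(-A[2, 2] - A[1, 2], 0)                # k20 = 0 w/o drainage
  A50 <- pk_system_matrix(tbl_params(drainage_ml_day = 50))
  expect_equal(-A50[2, 2] - A50[1, 2], (0.050 / 24) / 0.13)
})

test_that("zero clearances give a closed system and mass balance holds", {
  p <- pk_params(cl1 = 0)       # closed system (drainage 0 too)
  A <- pk_system_matrix(p)
  expect_equal(colSums(A), c(0, 0, 0), tolerance = 1e-15)
  reg <- regimen(1000, 8, 0.5)
  times <- c(0.1, 0.25, 0.5, 1, 3, 8)
  prof <- simulate_doses(p, reg, 1, times)
  administered <- reg$rate_mg_h * pmin(times, reg$infusion_h)
  expect_equal(rowSums(prof$amounts), administered, tolerance = 1e-8)
})

test_that("eigenvalues have negative real part for valid parameters", {
  set.seed(11)
  for (i in 1:20) {
    ev <- eigen(pk_system_matrix(rand_params()), only.values = TRUE)$values
    expect_true(all(Re(ev) < 0))
  }
})

test_that("matrix-exponential propagation matches adaptive ODE solving", {
  skip_if_not_installed("deSolve")
  set.seed(42)
  times <- c(0.25, 1, 2, 3.99, 4.5, 8, 12, 16)
  for (i in 1:20) {
    p <- rand_params()
    reg <- regimen(2000, 8, 4)
    got <- t(simulate_doses(p, reg, 2, times)$amounts)
    ref <- ode_oracle(p, reg, 2, times)
    expect_equal(got, ref, tolerance = 1e-6)
  }
})

test_that("continuous-infusion steady state matches the closed forms", {
  p <- tbl_params()  # drainage 0: C1 = R/CL1 and C2 = PC*Q1*C1/(Q1+CL2)
  prof <- steady_state_profile(p, regimen(4000, 8, continuous = TRUE),
                               times = c(0, 5, 8))
  expect_equal(prof$conc_plasma, rep(500 / 22.2, 3), tolerance = 1e-8)
  cl2 <- csf_clearance(p)
  expect_equal(prof$conc_csf,
               rep(0.172 * 0.010 * (500 / 22.2) / (0.010 + cl2), 3),
               tolerance = 1e-8)
  # 2 g q8h as continuous infusion means 250 mg/h
  prof2 <- steady_state_profile(p, regimen(2000, 8, continuous = TRUE),
                                times = 4)
  expect_equal(prof2$conc_plasma, 250 / 22.2, tolerance = 1e-8)
  expect_equal(prof2$conc_csf, 0.172 * 250 / 22.2, tolerance = 1e-8)
})

test_that("periodic steady state is a fixed point of the interval map", {
  p <- tbl_params(drainage_ml_day = 126)
  reg <- regimen(2000, 8, 4)
  x0 <- steady_state_amounts(p, reg)
  prof <- steady_state_profile(p, reg, times = c(0, reg$interval_h))
  x_tau <- prof$amounts[2, ]
  expect_lt(sqrt(sum((x_tau - x0)^2)) / sqrt(sum(x0^2)), 1e-10)
})

test_that("analytic steady state equals brute-force repeated dosing", {
  p <- tbl_params(drainage_ml_day = 126)
  reg <- regimen(2000, 8, 4)
  x0 <- steady_state_amounts(p, reg)
  brute <- simulate_doses(p, reg, 31, times = 30 * 8)$amounts[1, ]
  expect_equal(unname(brute), unname(x0), tolerance = 1e-4)  # < 0.01%
})

test_that("concentrations scale linearly with dose", {
  p <- tbl_params(drainage_ml_day = 50)
  times <- seq(0, 8, length.out = 41)
  base <- steady_state_profile(p, regimen(1000, 8, 2), times = times)
  for (c_scale in c(0.5, 2)) {
    scaled <- steady_state_profile(p, regimen(1000 * c_scale, 8, 2),
                                   times = times)
    expect_equal(scaled$conc_plasma, c_scale * base$conc_plasma,
                 tolerance = 1e-10)
    expect_equal(scaled$conc_csf, c_scale * base$conc_csf,
                 tolerance = 1e-10)
  }
  zero <- steady_state_profile(p, regimen(0, 8, 2), times = times)
  expect_true(all(zero$conc_plasma == 0) && all(zero$conc_csf == 0))
})

test_that("steady-state CSF exposure is non-increasing in drainage", {
  aucs <- vapply(c(0, 50, 150, 250, 350), function(d)
    profile_auc(steady_state_profile(tbl_params(drainage_ml_day = d),
                                     regimen(2000, 8, 4)), "csf"),
    numeric(1))
  expect_true(all(diff(aucs) < 0))
})

test_that("profiles satisfy conc = amount / volume and export tidily", {
  p <- tbl_params(drainage_ml_day = 50)
  prof <- steady_state_profile(p, regimen(1000, 6, 1), n_grid = 100)
  expect_equal(prof$conc_plasma, prof$amounts[, 1] / p$v1)
  expect_equal(prof$conc_csf, prof$amounts[, 2] / p$v2)
  expect_true(all(prof$conc_plasma >= 0) && all(prof$conc_csf >= 0))
  f <- tempfile(fileext = ".csv")
  write_profile(prof, f)
  df <- read.csv(f)
  expect_named(df, c("time_h", "conc_plasma_mg_l", "conc_csf_mg_l"))
  expect_equal(nrow(df), 101)
  unlink(f)
  expect_error(steady_state_profile(p, regimen(1000, 6, 1), times = 7),
               "within")
})
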