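# Synthetic trial generator: structure, covariates, reproducibility.

test_that("the default design reproduces the trial structure", {
  ds <- generate_study(study_design(), pop_spec(), seed = 1)
  d <- ds$data
  expect_equal(length(unique(d$ID)), 82)
  reg_counts <- table(ds$truth$regimen)
  expect_equal(as.integer(reg_counts[c("1g q8h", "1g q6h", "2g q8h")]),
               c(42, 19, 21))
  obs <- d[d$EVID == 0, ]
  expect_equal(sum(obs$CMT == 1), 82 * 4)   # 328 plasma rows
  expect_equal(sum(obs$CMT == 2), 82 * 4)   # 328 CSF rows
  expect_equal(sum(d$EVID == 1), 82 * 4)    # four dose events each
  expect_equal(as.integer(table(ds$truth$sampling_group)), c(40, 42))
  # dose events precede observations within each subject
  for (id in c(1, 40, 82)) {
    di <- d[d$ID == id, ]
    expect_lt(max(di$TIME[di$EVID == 1]), min(di$TIME[di$EVID == 0]))
  }
  # infusion rate 1 g/h
  expect_true(all(d$RATE[d$EVID == 1] == 1000))
})

test_that("covariates respect the design bounds and moments", {
  ds <- generate_study(study_design(), pop_spec(), seed = 2)
  tr <- ds$truth
  expect_true(all(tr$drainage_ml_day >= 0 & tr$drainage_ml_day <= 350))
  expect_true(all(tr$age >= 19 & tr$age <= 77))
  expect_true(all(tr$weight >= 41.5 & tr$weight <= 100))
  expect_equal(sum(tr$sex == "M"), 50)
  expect_true(all(tr$scr > 0))
  expect_equal(cockcroft_gault(tr$age, tr$weight, tr$scr, tr$sex),
               tr$clcr)
  # means converge to the design means (3 SEM at n = 82 per covariate)
  expect_lt(abs(mean(tr$age) - 43.4), 3 * 13.1 / sqrt(82))
  expect_lt(abs(mean(tr$weight) - 65.2), 3 * 11.6 / sqrt(82))
  expect_lt(abs(mean(tr$drainage_ml_day) - 126), 3 * 81 / sqrt(82) + 10)
})

test_that("noise-free generation equals the deterministic prediction", {
  spec0 <- pop_spec(bsv_cv = c(), residual_cv = 0)
  ds <- generate_study(small_design(8), spec0, seed = 3)
  d <- ds$data
  for (id in unique(d$ID)) {
    di <- d[d$ID == id, ]
    obs <- di[di$EVID == 0, ]
    reg <- regimen(di$AMT[di$EVID == 1][1],
                   diff(di$TIME[di$EVID == 1])[1],
                   di$AMT[di$EVID == 1][1] / 1000)
    p <- pk_params(drainage_ml_day = di$DRAIN[1])
    prof <- simulate_doses(p, reg, 4, obs$TIME[obs$CMT == 1])
    expect_equal(obs$DV[obs$CMT == 1], prof$conc_plasma, tolerance = 1e-10)
    expect_equal(obs$DV[obs$CMT == 2], prof$conc_csf, tolerance = 1e-10)
  }
})

test_that("generation is seed-reproducible and round-trips through CSV", {
  ds1 <- generate_study(study_design(), pop_spec(), seed = 11)
  ds2 <- generate_study(study_design(), pop_spec(), seed = 11)
  expect_identical(ds1$data, ds2$data)
  expect_identical(ds1$truth, ds2$truth)
  stem <- tempfile()
  write_study(ds1, stem)
  back <- read_study(paste0(stem, ".csv"))
  expect_equal(back$data$DV, ds1$data$DV)
  expect_equal(back$truth$cl1, ds1$truth$cl1)
  unlink(paste0(stem, c(".csv", "_truth.csv")))
})

test_that("optional missingness drops observations only", {
  des <- study_design(missing_frac = 0.2)
  ds <- generate_study(des, pop_spec(), seed = 4)
  obs_n <- sum(ds$data$EVID == 0)
  expect_lt(obs_n, 82 * 8)
  expect_equal(sum(ds$data$EVID == 1), 82 * 4)
})

test_that("Cockcroft-Gault matches hand-evaluated cases", {
  expect_equal(cockcroft_gault(40, 70, 1.0, "M"), 100 * 70 / 72)
  expect_equal(cockcroft_gault(40, 70, 1.0, "F"), 100 * 70 / 72 * 0.85,
               tolerance = 1e-12)
  expect_equal(round(cockcroft_gault(40, 70, 1.0, "M"), 2), 97.22)
  expect_equal(round(cockcroft_gault(40, 70, 1.0, "F"), 2), 82.64)
  expect_equal(cockcroft_gault(140, 70, 1.0, "M"), 0)   # boundary
  expect_error(cockcroft_gault(40, 70, 0, "M"), "scr")
})
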