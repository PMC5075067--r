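# Workflow entry points: factorial PTA reporting and determinism.

test_that("a single-regimen single-MIC run yields one row per target", {
  out <- withr::local_tempdir()
  res <- run_simulate_pta(out, regimens = list(`2g q8h` = regimen(2000, 8)),
                          infusion_h = 4, drainage_ml_day = 50,
                          mics = 8, n = 30, seed = 1, plot = FALSE)
  expect_equal(nrow(res$grid), 3)                  # one per target
  expect_equal(unique(res$grid$mic_mg_l), 8)
  expect_true(file.exists(file.path(out, "pta.csv")))
  expect_true(file.exists(file.path(out, "breakpoints.csv")))
  expect_true(file.exists(file.path(out, "recommendation.json")))
  # outputs embed version, config hash and seed
  hdr <- readLines(file.path(out, "pta.csv"), n = 3)
  expect_match(hdr[1], "meropk")
  expect_match(hdr[2], "config_hash")
  expect_match(hdr[3], "seed 1")
  rec <- jsonlite::read_json(file.path(out, "recommendation.json"))
  expect_equal(rec$seed, 1)
  expect_true(!is.null(rec$config_hash))
})

test_that("reruns with the same seed are byte-identical; overwrites refuse", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  args <- list(regimens = list(`2g q8h` = regimen(2000, 8)),
               infusion_h = c(1, 4), drainage_ml_day = c(50, 250),
               mics = c(0.5, 8), n = 40, seed = 7, plot = FALSE)
  do.call(run_simulate_pta, c(list(out1), args))
  do.call(run_simulate_pta, c(list(out2), args))
  for (f in c("pta.csv", "breakpoints.csv", "recommendation.json"))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  expect_error(do.call(run_simulate_pta, c(list(out1), args)), "force")
  res3 <- suppressMessages(do.call(run_simulate_pta,
                                   c(list(out1), args, force = TRUE)))
  expect_true(is.data.frame(res3$grid))
})

test_that("the recommendation maximizes the CSF breakpoint ordering", {
  out <- withr::local_tempdir()
  res <- run_simulate_pta(out, infusion_h = c(0.5, 4, Inf),
                          mics = 2^seq(-5, 6), n = 120, seed = 3,
                          plot = FALSE)
  rec <- res$recommendation
  # the non-CI scenario with the largest limited-drainage CSF breakpoint
  expect_equal(rec$recommended_regimen, "2 g q8h, 4-h infusion")
  expect_equal(rec$infusion_h, 4)
  expect_true(is.finite(rec$infusion_h))
  bp <- res$breakpoints
  bp <- bp[bp$pta_floor == 0.90 & is.finite(bp$infusion_h) &
             bp$drainage_ml_day <= 150 & bp$matrix == "csf" &
             bp$target_fraction == 0.5, ]
  worst <- tapply(bp$breakpoint_mg_l,
                  paste(bp$regimen, bp$infusion_h), min)
  expect_equal(unname(worst[paste(rec$recommended_regimen, 4)]),
               max(worst, na.rm = TRUE),
               tolerance = 1e-12)
})
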