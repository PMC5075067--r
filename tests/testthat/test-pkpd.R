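# fT>MIC computation and Monte Carlo PTA.

test_that("fT>MIC handles constant and crossing profiles exactly", {
  flat <- conc_profile(0:100, rep(10, 101), rep(10, 101))
  plasma40 <- pkpd_target("plasma", 0.40)       # free fraction 0.98
  expect_equal(ft_above_mic(flat, 8, plasma40), 1)    # 9.8 > 8
  expect_equal(ft_above_mic(flat, 12, plasma40), 0)
  expect_equal(ft_above_mic(flat, 9.8, plasma40), 0)  # strict inequality
  # mono-exponential toy: C(t) = 16 * 2^-t over tau = 8, crosses MIC 1 at t = 4
  tt <- 8 * (0:999) / 1000
  toy <- conc_profile(tt, 16 * 2^-tt, 16 * 2^-tt)
  expect_equal(ft_above_mic(toy, 1, pkpd_target("csf", 0.5)), 0.5)
  expect_error(ft_above_mic(toy, 0, plasma40), "mic")
  expect_error(ft_above_mic(toy, -1, plasma40), "mic")
})

test_that("target constructors validate and default free fractions", {
  expect_equal(pkpd_target("plasma", 0.4)$free_fraction, 0.98)
  expect_equal(pkpd_target("csf", 1)$free_fraction, 1)
  expect_error(pkpd_target("plasma", 0), "threshold_fraction")
  expect_error(pkpd_target("plasma", 1.2), "threshold_fraction")
  tg <- default_targets()
  expect_named(tg, c("plasma_40", "csf_50", "csf_100"))
})

test_that("PTA is monotone in MIC and certain at negligible MIC", {
  spec <- pop_spec()
  g <- pta(spec, regimen(2000, 8, 4), default_targets(),
           mics = c(1e-6, 2^seq(-5, 6)), drainage_ml_day = 50,
           n = 200, seed = 21)
  expect_true(all(g$pta >= 0 & g$pta <= 1))
  for (sp in split(g, g[c("matrix", "target_fraction")], drop = TRUE)) {
    sp <- sp[order(sp$mic_mg_l), ]
    expect_true(all(diff(sp$pta) <= 0))
    expect_equal(sp$pta[1], 1)        # MIC 1e-6
  }
  expect_error(pta(spec, regimen(2000, 8, 4), default_targets(),
                   mics = numeric(0)), "non-empty")
  expect_error(pta(spec, regimen(2000, 8, 4), default_targets(),
                   mics = c(1, -1)), "> 0")
})

test_that("the 100% target never beats the 50% target", {
  cohort <- sample_individuals(pop_spec(), 200, seed = 22)
  g <- pta(pop_spec(), regimen(1000, 8, 2),
           list(pkpd_target("csf", 0.5), pkpd_target("csf", 1)),
           mics = 2^seq(-5, 2), drainage_ml_day = 50, cohort = cohort)
  g50 <- g[g$target_fraction == 0.5, ]
  g100 <- g[g$target_fraction == 1, ]
  expect_true(all(g100$pta <= g50$pta))
})

test_that("CSF PTA falls with drainage; plasma PTA does not change", {
  spec <- pop_spec()
  cohort <- sample_individuals(spec, 300, seed = 23)
  mics_csf <- c(0.25, 0.5, 1)
  csf_by_drain <- sapply(c(0, 50, 150, 250), function(d)
    pta(spec, regimen(2000, 8, 4), pkpd_target("csf", 0.5),
        mics = mics_csf, drainage_ml_day = d, cohort = cohort)$pta)
  for (i in seq_along(mics_csf))
    expect_true(all(diff(csf_by_drain[i, ]) <= 0))
  plasma_by_drain <- sapply(c(0, 250), function(d)
    pta(spec, regimen(2000, 8, 4), pkpd_target("plasma", 0.4),
        mics = c(2, 8, 16), drainage_ml_day = d, cohort = cohort)$pta)
  expect_lt(max(abs(plasma_by_drain[, 1] - plasma_by_drain[, 2])), 0.02)
})

test_that("longer infusions attain targets at least as often (shared cohort)", {
  # Monotonicity in infusion duration holds in the trough-limited regime
  # (MIC below the continuous-infusion plateau). Exactly at the capacity
  # edge a finite infusion's higher within-infusion plateau can beat
  # continuous infusion for sub-100% thresholds, so continuous infusion
  # is compared against the shortest infusion rather than asserted
  # globally maximal.
  spec <- pop_spec()
  cohort <- sample_individuals(spec, 150, seed = 24)
  pta_at <- function(reg, tgt, mic)
    pta(spec, reg, tgt, mics = mic, drainage_ml_day = 50,
        cohort = cohort)$pta
  for (case in list(list(pkpd_target("plasma", 0.4), 8),
                    list(pkpd_target("csf", 0.5), 0.5))) {
    vals <- vapply(c(0.5, 1, 2, 4), function(D)
      pta_at(regimen(2000, 8, D), case[[1]], case[[2]]), numeric(1))
    expect_true(all(diff(vals) >= 0))
    ci <- pta_at(regimen(2000, 8, continuous = TRUE), case[[1]],
                 case[[2]])
    expect_gte(ci, vals[1])
  }
})

test_that("replicate PTA runs with different seeds agree within noise", {
  spec <- pop_spec()
  mics <- 2^seq(-5, 6)
  g1 <- pta(spec, regimen(2000, 8, 4), default_targets(), mics,
            drainage_ml_day = 50, n = 1000, seed = 31)
  g2 <- pta(spec, regimen(2000, 8, 4), default_targets(), mics,
            drainage_ml_day = 50, n = 1000, seed = 32)
  # binomial noise bound: 4 SE of the difference of two proportions
  # (a 3-SE bound is exceeded by chance too easily across 36 grid points)
  se <- sqrt(g1$pta * (1 - g1$pta) / 1000 + g2$pta * (1 - g2$pta) / 1000)
  expect_true(all(abs(g1$pta - g2$pta) <= pmax(4 * se, 5 / 1000)))
  expect_lt(max(abs(g1$pta - g2$pta)), 0.06)
})

test_that("breakpoints pick the highest qualifying MIC", {
  spec <- pop_spec()
  g <- pta(spec, regimen(2000, 8, 4), default_targets(),
           mics = 2^seq(-5, 6), drainage_ml_day = 50, n = 100, seed = 25)
  bp <- pkpd_breakpoint(g, 0.90)
  expect_equal(nrow(bp), 3)
  for (i in seq_len(nrow(bp))) {
    gi <- g[g$matrix == bp$matrix[i] &
              g$target_fraction == bp$target_fraction[i], ]
    if (is.na(bp$breakpoint_mg_l[i])) {
      expect_true(all(gi$pta < 0.9))
    } else {
      expect_gte(gi$pta[gi$mic_mg_l == bp$breakpoint_mg_l[i]], 0.9)
      expect_true(all(gi$pta[gi$mic_mg_l > bp$breakpoint_mg_l[i]] < 0.9))
    }
  }
  # degenerate grids
  all1 <- g; all1$pta <- 1
  expect_equal(unique(pkpd_breakpoint(all1, 0.9)$breakpoint_mg_l), 64)
  all0 <- g; all0$pta <- 0
  expect_true(all(is.na(pkpd_breakpoint(all0, 0.9)$breakpoint_mg_l)))
})
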