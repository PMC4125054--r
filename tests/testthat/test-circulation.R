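test_that("blood exits pick organs proportionally to entry rates", {
  body <- bodyConfig()
  expect_equal(bloodExitRate(body), 2.5)
  set.seed(301)
  draws <- replicate(3000, {
    s <- stepBlood(body)
    c(spleen = s$organ == "spleen", dwell = s$dwell_h)
  })
  expect_equal(mean(draws["spleen", ]), 0.4, tolerance = 0.08)
  expect_equal(mean(draws["dwell", ]) * 60, 24, tolerance = 0.05)
  # essentially single-organ body: spleen rate dwarfs the LN rates
  solo <- bodyConfig(spleen_entry_rate = 1, ln_entry_total = 1e-9)
  set.seed(302)
  expect_true(all(replicate(50, stepBlood(solo)$organ) == "spleen"))
})

test_that("time-varying dLN rates: ramp shapes and thinned sojourn law", {
  body <- bodyConfig(dln_count = 2, ramp = entryRateRamp(9, 4.5))
  dln_rate <- sum(body$ln_entry_rates[body$dln_spheres])
  expect_equal(bloodExitRate(body, -1), 2.5)
  expect_equal(bloodExitRate(body, 54), 2.5 + 4 * dln_rate)   # half ramp
  expect_equal(bloodExitRate(body, 200), 2.5 + 8 * dln_rate)  # post ramp
  step <- bodyConfig(dln_count = 2, ramp = entryRateRamp(9, shape = "step"))
  expect_equal(bloodExitRate(step, 1e-9), 2.5 + 8 * dln_rate)

  # thinning reproduces the inhomogeneous exit-time law: compare the
  # empirical sojourn CDF against fine-grained numerical integration of
  # Lambda(t) on an exaggerated ramp
  fast <- bodyConfig(dln_count = 2, ln_entry_total = 1.5,
                     ramp = entryRateRamp(40, ramp_end_days = 1 / 6))
  set.seed(303)
  waits <- replicate(4000, stepBlood(fast, t = 0)$dwell_h)
  tgrid <- seq(0, 8, by = 0.001)
  lam <- bloodExitRate(fast, tgrid)
  surv <- exp(-cumsum(lam) * 0.001)
  cdf_num <- function(q) 1 - approx(tgrid, surv, xout = q, rule = 2)$y
  expect_gt(suppressWarnings(ks.test(waits, cdf_num))$p.value, 0.01)
})

test_that("trajectories are contiguous and respect the transit mode", {
  set.seed(304)
  sim <- simulateCohort(50, horizon = 100, burn_in = FALSE,
                        mode = transitMode("deterministic", T_det = 12))
  ep <- sim$episodes
  for (cl in unique(ep$cell_id)) {
    e <- ep[ep$cell_id == cl, ]
    expect_equal(e$t_entry_h[1], 0)            # burn-in disabled: blood at 0
    expect_equal(e$compartment[1], 0L)
    expect_true(all(abs(e$t_entry_h[-1] - e$t_exit_h[-nrow(e)]) < 1e-9))
    expect_lte(max(e$t_exit_h), 100 + 1e-9)
  }
  # every completed LN episode lasts exactly T_det
  ln <- ep[ep$compartment >= 2 & ep$t_exit_h < 100, ]
  expect_true(all(abs(ln$t_exit_h - ln$t_entry_h - 12) < 1e-9))
  # spleen episodes remain stochastic
  sp <- ep[ep$compartment == 1 & ep$t_exit_h < 100, ]
  expect_gt(length(unique(round(sp$t_exit_h - sp$t_entry_h, 6))), 5)
})

test_that("long-run occupancy matches the renewal-reward prediction", {
  set.seed(305)
  sim <- simulateCohort(3000, horizon = 336)
  occ <- occupancyFractions(sim)
  # rate x mean-dwell shares: blood 1/Lambda, spleen and LN weighted by
  # their pick probabilities
  sp_mean <- mean(sampleSpleenTransit(4000, spleenSection()))
  cyc <- c(blood = 1 / 2.5, spleen = 0.4 * sp_mean, ln = 0.6 * 13.5)
  expect_equal(unname(occ), unname(cyc / sum(cyc)), tolerance = 0.04)
  # occupancy at t = 0 after burn-in agrees with the long-run average
  expect_equal(unname(occupancyAt(sim, 0)), unname(occ), tolerance = 0.06)
  # two seeds give statistically indistinguishable occupancy at t = 0
  set.seed(306)
  sim2 <- simulateCohort(3000, horizon = 10)
  n_in <- function(s, at) {
    sel <- s$episodes$t_entry_h <= at & s$episodes$t_exit_h > at
    table(factor(ifelse(s$episodes$compartment[sel] == 0, "blood",
                        ifelse(s$episodes$compartment[sel] == 1, "spleen", "ln")),
                 levels = c("blood", "spleen", "ln")))
  }
  tab <- rbind(n_in(sim, 0), n_in(sim2, 0))
  expect_gt(chisq.test(tab)$p.value, 0.01)
})

test_that("same seed reproduces the simulation exactly", {
  set.seed(307); a <- simulateCohort(100, horizon = 50)
  set.seed(307); b <- simulateCohort(100, horizon = 50)
  expect_identical(a$episodes, b$episodes)
})

test_that("arrival times follow the documented conventions", {
  set.seed(308)
  body <- bodyConfig(dln_count = 3)
  sim <- simulateCohort(2000, body, horizon = 150)
  arr <- arrivalTimes(sim, "spleen")
  # cells inside the spleen at t = 0 count as arrived immediately
  expect_equal(mean(arr == 0, na.rm = TRUE),
               unname(occupancyAt(sim, 0)["spleen"]), tolerance = 0.02)
  arr2 <- arrivalTimes(sim, "spleen", include_initial = FALSE)
  expect_true(all(arr2[!is.na(arr2)] > 0))
  # arrival anywhere coincides with the first blood exit
  arr_any <- arrivalTimes(sim, "ln")
  expect_true(all(is.na(arr_any) | arr_any >= 0))
  # dLN arrival hazard per blood exit ~ sum of dLN rates over Lambda
  first_dln <- arrivalTimes(sim, "dln", include_initial = FALSE)
  expect_gt(mean(!is.na(first_dln) & first_dln <= 150), 0.3)
  expect_error(arrivalTimes(sim, integer(0)), "empty target")
})

test_that("ndLN depletion: flat without dLNs, faster with an entry ramp", {
  prm <- primingParams(1, 1, 4)
  set.seed(309)
  none <- simulateCohort(400, bodyConfig(), horizon = 100, priming = prm)
  flat <- ndlnDepletionCurve(none, times = c(0, 48, 96))
  expect_equal(flat$fraction_outside, rep(1, 3))

  body_r <- bodyConfig(dln_count = 2, ramp = entryRateRamp(9, 4.5))
  body_n <- bodyConfig(dln_count = 2)
  set.seed(310)
  with_r <- simulateCohort(1500, body_r, horizon = 120, priming = prm)
  set.seed(311)
  no_r <- simulateCohort(1500, body_n, horizon = 120, priming = prm)
  cr <- ndlnDepletionCurve(with_r, times = c(0, 96))
  cn <- ndlnDepletionCurve(no_r, times = c(0, 96))
  # at t = 0 the curve is 1 minus the initial dLN occupancy
  expect_equal(cr$fraction_outside[1], 1 - mean(with_r$initial_dln),
               tolerance = 0.02)
  expect_lt(cr$fraction_outside[2], cn$fraction_outside[2])
})
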