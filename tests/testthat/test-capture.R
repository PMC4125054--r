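test_that("per-visit retention probability: limits, closed form, Poisson tail", {
  g <- lnSphere()
  # vanishing contact rate -> no retention; very long fixed dwell -> certain
  expect_lt(probRetainedPerVisit(primingParams(1e-6, 1, 1), geom = g), 1e-4)
  expect_equal(probRetainedPerVisit(primingParams(1, 1, 2),
                                    transitMode("deterministic", 1e4)), 1)
  # deterministic transit: Gamma CDF at the dwell (= Poisson tail)
  expect_equal(
    probRetainedPerVisit(primingParams(1, 1, 8),
                         transitMode("deterministic", 12)),
    1 - ppois(7, 12), tolerance = 1e-12)
  # probabilistic priming, stochastic transit: 1 - z csch z at z = 1
  g1 <- lnSphere(radius = 60)  # z = R sqrt(mu/M_h) = 1 at mu = 1, M = 60
  expect_equal(probRetainedPerVisit(primingParams(1, 1, 1), geom = g1),
               1 - 1 / sinh(1), tolerance = 1e-9)
  # n > 1 numeric integral vs Monte Carlo over sampled transits
  set.seed(401)
  p8 <- primingParams(1, 1, 8)
  trans <- sampleLnTransit(5e4, g)
  expect_equal(probRetainedPerVisit(p8, geom = g),
               mean(retentionCDF(trans, p8)), tolerance = 0.005)
})

test_that("closed-form capture time: components and Monte Carlo agreement", {
  p8 <- primingParams(1, 1, 8)
  # no-failure limit: only the truncated within-dLN time remains
  sol1 <- expectedCaptureTime(1, primingParams(100, 1, 1), T_det = 50, t0 = 0)
  expect_equal(sol1$E_N, 0, tolerance = 1e-6)
  expect_equal(sol1$expected_capture_h, sol1$theta)
  # reference components at f = 0.25, n = 8, T = 12
  sol <- expectedCaptureTime(0.25, p8, T_det = 12)
  expect_equal(sol$P, 0.9105, tolerance = 1e-4)
  expect_equal(sol$E_N, (1 - 0.25 * sol$P) / (0.25 * sol$P), tolerance = 1e-9)
  # truncated-Gamma mean identity against numerical integration
  theta_num <- integrate(function(a) a * dgamma(a, 8, 1), 0, 12)$value /
    pgamma(12, 8, 1)
  expect_equal(sol$theta, theta_num, tolerance = 1e-6)
  # Monte Carlo agreement
  set.seed(402)
  mc <- captureTimeMC(3000, 0.25, p8, transitMode("deterministic", 12))
  expect_lt(attr(mc, "censored"), 0.01)
  expect_equal(mean(mc, na.rm = TRUE), sol$expected_capture_h, tolerance = 0.1)
})

test_that("optimal transit matches a brute-force scan and its limits", {
  p2 <- primingParams(1, 1, 2)
  opt <- optimalTransitTime(0.25, p2)
  # independent oracle: direct grid evaluation of the capture formula
  tau_b <- meanInterVisitTime(bodyConfig())
  grid <- seq(0.5, 48, by = 0.01)
  gval <- vapply(grid, function(T) {
    P <- pgamma(T, 2, 1)
    (1 - 0.25 * P) / (0.25 * P) * (T + tau_b) +
      (2 / 1) * pgamma(T, 3, 1) / P
  }, numeric(1))
  expect_equal(as.numeric(opt), grid[which.min(gval)], tolerance = 0.02)
  # instant priming favors immediate egress
  fast <- optimalTransitTime(0.25, primingParams(1000, 1, 1))
  expect_lt(as.numeric(fast), 0.2)
})

test_that("benefit/risk: optimized transit wins at its dose, loses badly off-dose", {
  set.seed(403)
  m <- benefitRiskMatrix(optimized_for = 2, evaluated_at = c(2, 10),
                         n_cells = 1200)
  expect_lt(m["2", "2"], 1)      # benefit at the optimized dose
  expect_gt(m["2", "10"], 25)    # large risk at the unexpected dose
  expect_gt(m["2", "10"] / m["2", "2"], 40)
  expect_equal(as.numeric(attr(m, "optimal_transit_h")), 3.7, tolerance = 0.15)
})
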