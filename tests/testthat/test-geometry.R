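test_that("LN mean transit and radius calibration are consistent", {
  g <- lnSphere(radius = 540, motility = 60)
  expect_equal(lnMeanTransit(g), 13.5)
  g2 <- lnSphere(radius = 1080, motility = 60)
  expect_equal(lnMeanTransit(g2), 4 * 13.5)
  expect_equal(calibrateLnRadius(13.5, 60), 540)
  expect_equal(lnMeanTransit(lnSphere(calibrateLnRadius(7, 45), 45)), 7)
  expect_error(calibrateLnRadius(0), "positive")

  # integral of the survival function equals the closed-form mean
  m <- integrate(function(t) lnSurvival(t, g), 0, Inf, rel.tol = 1e-9)$value
  expect_equal(m, 13.5, tolerance = 1e-6)
})

test_that("survival series matches the explicit Brownian oracle", {
  g <- lnSphere()
  expect_identical(lnSurvival(0, g), 1)
  tt <- seq(0, 60, by = 0.5)
  s <- lnSurvival(tt, g)
  expect_true(all(diff(s) <= 1e-12))
  set.seed(201)
  walks <- sampleLnTransitBrownian(2000, g, dt = 0.1)
  emp <- vapply(tt, function(x) mean(walks > x), numeric(1))
  expect_lt(max(abs(emp - s)), 0.04)
})

test_that("series-based sampler reproduces the analytic transit law", {
  g <- lnSphere()
  set.seed(202)
  x <- sampleLnTransit(2e4, g)
  expect_true(all(x > 0))
  expect_equal(mean(x), 13.5, tolerance = 3 * sd(x) / sqrt(2e4) / 13.5)
  # entry-to-exit lag: almost no egress in the first hour
  expect_gt(quantile(x, 0.01), 1)
  cdf <- function(q) 1 - lnSurvival(q, g)
  expect_gt(suppressWarnings(ks.test(x[1:5000], cdf))$p.value, 0.01)
  # right tail is lighter than the exponential with the same mean
  expect_lt(mean(x > 3 * 13.5), exp(-3))
})

test_that("Laplace transform matches its closed form and the samples", {
  g <- lnSphere()
  expect_identical(lnTransitLaplace(0, g), 1)
  # z = R sqrt(s/M) = 1  =>  value 1/sinh(1)
  s1 <- (g$motility * 60) / g$radius^2
  expect_equal(lnTransitLaplace(s1, g), 1 / sinh(1), tolerance = 1e-10)
  set.seed(203)
  x <- sampleLnTransit(2e4, g)
  for (s in c(0.05, 0.2)) {
    expect_equal(mean(exp(-s * x)), lnTransitLaplace(s, g), tolerance = 0.01)
  }
})

test_that("spleen disc transit: guard, lag, aperture monotonicity, dt stability", {
  sp <- spleenSection()
  expect_error(sampleSpleenTransit(10, sp, dt = 5), "too coarse")
  set.seed(204)
  x <- sampleSpleenTransit(4000, sp)
  expect_equal(mean(x), 6, tolerance = 0.05)
  # entry and exit sites are separated: transit needs a minimum time
  expect_lt(mean(x < 0.5), 0.01)
  # lighter-than-exponential right tail at the same mean
  expect_lt(mean(x > 3 * mean(x)), exp(-3))
  # wider aperture drains faster
  wide <- spleenSection(aperture = 3.0)
  expect_lt(mean(sampleSpleenTransit(2000, wide)), mean(x))
  # halving the step changes the mean by < 5%
  xh <- sampleSpleenTransit(4000, sp, dt = 0.1)
  expect_lt(abs(mean(xh) - mean(x)) / mean(x), 0.05)
})

test_that("spleen aperture calibration recovers the stored default", {
  set.seed(205)
  geom <- calibrateSpleen(target_mean = 6, n_eval = 2000)
  expect_true(geom$aperture > 0 && geom$aperture < pi)
  expect_equal(geom$aperture, spleenSection()$aperture, tolerance = 0.15)
  cal <- attr(geom, "calibration")
  expect_equal(cal$achieved_mean_h, 6, tolerance = 0.05)
  # a longer target needs a narrower aperture
  set.seed(206)
  slower <- calibrateSpleen(target_mean = 9, n_eval = 1500)
  expect_lt(slower$aperture, geom$aperture)
  # unreachable target reports the bracket
  expect_error(calibrateSpleen(target_mean = 100, n_eval = 500), "not bracketed")
})
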