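test_that("retention CDF is the regularized incomplete gamma with rate lambda*p", {
  # exponential special case: n = 1, mu = 0.125/h at t = 8 h
  p1 <- primingParams(contact_rate = 0.125, success_prob = 1,
                      required_contacts = 1)
  expect_equal(retentionCDF(8, p1), 1 - exp(-1), tolerance = 1e-12)
  expect_identical(retentionCDF(0, p1), 0)

  # integer shape: CDF equals the Poisson tail P(Pois(mu t) >= n)
  p8 <- primingParams(1, 1, 8)
  expect_equal(retentionCDF(8, p8), 1 - ppois(7, 8), tolerance = 1e-12)
  expect_equal(retentionCDF(8, p8), 0.5470, tolerance = 1e-4)

  # identifiability: only mu = lambda p matters
  pa <- primingParams(contact_rate = 2, success_prob = 0.5, required_contacts = 4)
  pb <- primingParams(contact_rate = 1, success_prob = 1, required_contacts = 4)
  tt <- seq(0, 30, by = 0.25)
  expect_equal(retentionCDF(tt, pa), retentionCDF(tt, pb))
  expect_equal(successRate(pa), successRate(pb))

  expect_error(primingParams(-1, 1, 1), "contact_rate")
  expect_error(primingParams(1, 0, 1), "success_prob")
  expect_error(primingParams(1, 1, 0.5), "required_contacts")
  expect_error(retentionCDF(-1, p8), "must be finite and >= 0")
})

test_that("sampled retention times match the analytic law", {
  set.seed(101)
  # the two reference parameterizations: mean 8 h and 2 h
  for (cfg in list(list(n = 8, mean = 8), list(n = 2, mean = 2))) {
    p <- primingParams(1, 1, cfg$n)
    x <- sampleRetentionTime(1e5, p)
    expect_equal(mean(x), cfg$mean, tolerance = 0.02)
    ks <- suppressWarnings(
      ks.test(x[1:10000], pgamma, shape = cfg$n, rate = 1))
    expect_gt(ks$p.value, 0.01)
  }
  # exponential variance at n = 1, mu = 1
  v <- var(sampleRetentionTime(1e5, primingParams(1, 1, 1)))
  expect_equal(v, 1, tolerance = 0.05)
})

test_that("equal-mean laws: probabilistic priming is wider and crosses below", {
  for (m in c(2, 8)) {
    n <- if (m == 2) 2 else 8
    si <- primingParams(contact_rate = n / m, success_prob = 1,
                        required_contacts = n)
    pp <- primingParams(contact_rate = 1 / m, success_prob = 1,
                        required_contacts = 1)
    expect_equal(retentionMean(si), retentionMean(pp))
    expect_lt(retentionVariance(si), retentionVariance(pp))
    # gradual vs switch-like: PP CDF above SI at small t, below at large t
    expect_gt(retentionCDF(m / 4, pp), retentionCDF(m / 4, si))
    expect_lt(retentionCDF(3 * m, pp), retentionCDF(3 * m, si))
  }
})

test_that("event-level contact histories reproduce the Gamma law", {
  set.seed(102)
  # deterministic success: retention exactly at the 3rd contact
  p <- primingParams(2, 1, 3)
  h <- simulateContactHistory(p, horizon = 100)
  expect_equal(h$retention_time_h, h$events$time_h[3])

  # marginal retention-time law equals the Gamma law (mu = lambda p)
  pa <- primingParams(contact_rate = 2, success_prob = 0.5, required_contacts = 4)
  pb <- primingParams(contact_rate = 1, success_prob = 1, required_contacts = 4)
  ra <- replicate(600, simulateContactHistory(pa, 100)$retention_time_h)
  rb <- replicate(600, simulateContactHistory(pb, 100)$retention_time_h)
  expect_gt(suppressWarnings(ks.test(ra, rb))$p.value, 0.01)
  expect_gt(suppressWarnings(
    ks.test(ra, pgamma, shape = 4, rate = 1))$p.value, 0.01)

  # 1/8 success at one contact per hour: mean 8 h
  rc <- replicate(2000, simulateContactHistory(
    primingParams(1, 1 / 8, 1), 200)$retention_time_h)
  expect_equal(mean(rc, na.rm = TRUE), 8, tolerance = 0.1)
})

test_that("unique-contact factor is 2/3 and cannot be applied twice", {
  expect_equal(uniqueContactFactor(), 2 / 3)
  p <- primingParams(1.5, 1, 1)
  q <- applyUniqueContactFactor(p)
  expect_equal(q$contact_rate, 1.0)
  expect_error(applyUniqueContactFactor(q), "already applied")
})
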