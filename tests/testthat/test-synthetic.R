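test_that("generator output satisfies the track invariants and ground truth law", {
  set.seed(601)
  spec <- syntheticTrackSpec(n_experiments = 2,
                             doses = list(low = primingParams(2, 1, 8)),
                             cognate_per_video = 60, control_per_video = 60)
  gen <- generateTrackSet(spec)
  tr <- gen$tracks$tracks
  key <- interaction(tr$video_id, tr$track_id, drop = TRUE)
  expect_true(all(tapply(tr$t_min, key, function(x) all(diff(x) > 0))))
  expect_true(all(tapply(tr$t_min, key, length) >= 2))
  # controls never arrest
  gt <- gen$ground_truth
  expect_true(all(is.na(gt$retention_time_h[gt$cell_class == "control"])))
  # cognate arrest times follow the configured retention law
  a <- gt$retention_time_h[gt$cell_class == "cognate"]
  expect_gt(suppressWarnings(ks.test(a, pgamma, shape = 8, rate = 2))$p.value,
            0.01)
})

test_that("all-control sets produce only background retention", {
  set.seed(602)
  gen <- generateTrackSet(syntheticTrackSpec(
    n_experiments = 1, cognate_per_video = 0, control_per_video = 120))
  thr <- gateThreshold(gen$tracks)
  r <- retainedFraction(gen$tracks$tracks, thr)
  expect_lt(r, 0.25)
  expect_equal(backgroundCorrect(r, r), 0)
})

test_that("SI and PP ground truths yield their characteristic timecourses", {
  set.seed(603)
  si <- generateTrackSet(syntheticTrackSpec(
    n_experiments = 1, doses = list(low = primingParams(2, 1, 8)),
    cognate_per_video = 150, control_per_video = 150))
  win_si <- windowRetentionSeries(si$tracks)
  # switch-like: negligible early, high late
  expect_lt(mean(win_si$fraction[win_si$time_h < 2]), 0.1)
  expect_gt(mean(win_si$fraction[win_si$time_h > 7]), 0.75)

  set.seed(604)
  pp <- generateTrackSet(syntheticTrackSpec(
    n_experiments = 1, doses = list(low = primingParams(0.25, 1, 1)),
    cognate_per_video = 150, control_per_video = 150))
  win_pp <- windowRetentionSeries(pp$tracks)
  # gradual: already substantial in the first video (no shoulder)
  expect_gt(mean(win_pp$fraction[win_pp$time_h < 2]), 0.15)
  # and the early-time ordering flips between the two families
  expect_gt(mean(win_pp$fraction[win_pp$time_h < 2]),
            mean(win_si$fraction[win_si$time_h < 2]))
})

test_that("persistent walks reproduce the configured motility on long tracks", {
  set.seed(605)
  # long observation windows so the persistence correction (~tau over the
  # mean displacement lag) stays small
  gen <- generateTrackSet(syntheticTrackSpec(
    n_experiments = 1, video_times_h = 0, cognate_per_video = 0,
    control_per_video = 120, video_min = 180, track_mean_min = 1e4))
  s <- tcellsurv:::.trackSummaries(gen$tracks$tracks)
  long <- s[s$n_frames >= 500, ]
  expect_gt(nrow(long), 40)
  expect_equal(mean(long$motility), 60, tolerance = 0.10)
})

test_that("circulation fixtures encode the documented scenarios", {
  hsv <- circulationFixture("hsv_like")
  expect_length(hsv$body$dln_spheres, 2)
  expect_equal(hsv$body$ramp$fold, 9)
  expect_equal(hsv$body$ramp$ramp_end_h, 4.5 * 24)
  flu <- circulationFixture("influenza_like")
  expect_length(flu$body$dln_spheres, 9)
  # dLN designations point at single-sphere LNs
  tab <- table(flu$body$sphere_ln)
  expect_true(all(tab[flu$body$sphere_ln[flu$body$dln_spheres]] == 1))
  fig <- circulationFixture("fig_hypothetical")
  expect_equal(fig$dln_fraction, 0.25)
  expect_equal(fig$priming$required_contacts, 8)
  expect_equal(successRate(fig$priming), 1)
  base <- circulationFixture("baseline")
  expect_length(base$body$dln_spheres, 0)
  expect_error(circulationFixture("smallpox"), "arg")
})
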