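test_that("motility coefficient: exact small cases and invariances", {
  # stationary cell
  still <- data.frame(t_min = 0:4, x_um = 1, y_um = 2, z_um = 3)
  expect_equal(motilityCoefficient(still), 0)
  # even-length track: middle is the average of the two central samples
  tr <- data.frame(t_min = c(0, 1, 2, 3), x_um = c(0, 1, 3, 6),
                   y_um = 0, z_um = 0)
  mid <- (1 + 3) / 2; t_mid <- 1.5
  d2 <- (c(0, 1, 3, 6) - mid)^2
  expect_equal(motilityCoefficient(tr),
               sum(d2) / (6 * sum(abs(c(0, 1, 2, 3) - t_mid))))
  # coordinate scaling by c multiplies the estimate by c^2
  tr2 <- tr; tr2[, c("x_um", "y_um", "z_um")] <- tr2[, c("x_um", "y_um", "z_um")] * 3
  expect_equal(motilityCoefficient(tr2), 9 * motilityCoefficient(tr))
  expect_error(motilityCoefficient(data.frame(t_min = 1, x_um = 0, y_um = 0,
                                              z_um = 0)), "at least 2")
  expect_error(motilityCoefficient(c(0, 0, 1), matrix(0, 3, 3)),
               "strictly increasing")
})

test_that("estimator is unbiased for Brownian tracks, biased low for short persistent walks", {
  set.seed(501)
  est <- replicate(800, {
    tr <- brownian_track(61, dt = 1 / 3, M = 60)
    motilityCoefficient(tr$t, tr$xyz)
  })
  expect_equal(mean(est), 60, tolerance = 0.05)
  # single-track estimates scatter widely (few effective degrees of
  # freedom) but stay centred: the median sits within 15% of the truth
  expect_equal(median(est), 60, tolerance = 0.15)

  # persistent walk sampled over few frames: documented downward bias
  set.seed(502)
  gen <- generateTrackSet(syntheticTrackSpec(
    n_experiments = 1, video_times_h = 0, cognate_per_video = 0,
    control_per_video = 150, track_mean_min = 3))
  s <- tcellsurv:::.trackSummaries(gen$tracks$tracks)
  short <- s[s$n_frames < 10, ]
  expect_gt(nrow(short), 20)
  expect_lt(mean(short$motility), 0.9 * 60)
})

test_that("weighted median and gating threshold", {
  # expansion by integer weights: {1, 3, 10, 10} -> midpoint 6.5
  expect_equal(weightedMedian(c(1, 3, 10), c(1, 1, 2)), 6.5)
  expect_equal(weightedMedian(c(5, 5, 5), c(2, 1, 7)), 5)
  expect_equal(weightedMedian(c(2, 8), c(1, 3)), 8)
  expect_error(weightedMedian(1:3, c(1, -1, 1)), "invalid weights")

  set.seed(503)
  tracks <- track_table(c(
    lapply(1:20, function(i) c(brownian_track(31, M = 50), class = "control")),
    lapply(1:5, function(i) c(brownian_track(31, M = 50), class = "cognate"))))
  thr <- gateThreshold(tracks, gamma = 0.4)
  expect_equal(as.numeric(thr) / attr(thr, "weighted_median"), 0.4)
  expect_equal(attr(thr, "weighted_median"), 50, tolerance = 0.35)
  expect_error(gateThreshold(tracks[tracks$cell_class == "cognate", ]),
               "no control tracks")
})

test_that("duration-weighted retained fraction and background correction", {
  s <- data.frame(motility = c(1, 30), duration_min = c(40, 20))
  expect_equal(retainedFraction(s, 10), 2 / 3)
  expect_equal(retainedFraction(s, 0.5), 0)
  expect_equal(retainedFraction(s, Inf), 1)
  # invariant to ordering and duplication of the whole set
  expect_equal(retainedFraction(s[2:1, ], 10), 2 / 3)
  expect_equal(retainedFraction(rbind(s, s), 10), 2 / 3)
  # nondecreasing in the threshold
  thr <- c(0.5, 5, 20, 50)
  fr <- vapply(thr, retainedFraction, numeric(1), summaries = s)
  expect_true(all(diff(fr) >= 0))

  expect_equal(backgroundCorrect(0.2, 0.2), 0)
  expect_equal(backgroundCorrect(1, 0.3), 1)
  expect_equal(backgroundCorrect(0.5, 0.2), 0.375)
  expect_equal(backgroundCorrect(0.1, 0.4), 0)
  expect_equal(backgroundCorrect(0.5, 0.2, method = "subtract"), 0.3)
  expect_error(backgroundCorrect(0.5, 1), "r_ctrl")
})

test_that("window splitting conserves duration and stamps times post entry", {
  set.seed(504)
  # two cognate tracks: one inside a window, one crossing both boundaries,
  # plus controls for the gate
  cog1 <- c(brownian_track(16, dt = 1, M = 60), class = "cognate")   # 0-15 min
  cog2 <- c(brownian_track(51, dt = 1, M = 60), class = "cognate")   # 0-50 min
  cog2$t <- cog2$t + 5                                               # 5-55 min
  ctrl <- lapply(1:10, function(i) c(brownian_track(31, dt = 1, M = 60),
                                     class = "control"))
  tracks <- track_table(c(list(cog1, cog2), ctrl))
  videos <- data.frame(video_id = "v1", experiment_id = "e1",
                       time_post_transfer_h = 3, entry_offset_h = 1,
                       duration_min = 60)
  ts <- trackSet(tracks, videos)
  win <- windowRetentionSeries(ts, min_duration_min = 0)
  expect_equal(nrow(win), 3)  # a 60-min video yields exactly 3 windows
  expect_equal(win$time_h, 3 - 1 + c(10, 30, 50) / 60)
  # total cognate duration (15 + 50 min) is conserved across windows
  expect_equal(sum(win$weight_min), 65)
  expect_error(windowRetentionSeries(trackSet(tracks, within(videos,
    duration_min <- 15))), "window longer")
})

test_that("windowed pipeline recovers a switch-like retention timecourse", {
  set.seed(505)
  # ground truth switching at ~4.5 h post entry (24 contacts at 5.33/h)
  spec <- syntheticTrackSpec(
    n_experiments = 1,
    doses = list(mid = primingParams(16 / 3, 1, 24)),
    video_times_h = c(3, 6),
    cognate_per_video = 250, control_per_video = 250)
  gen <- generateTrackSet(spec)
  win <- windowRetentionSeries(gen$tracks)
  early <- win$fraction[win$time_h < 4]
  late <- win$fraction[win$time_h > 6]
  expect_lt(mean(early), 0.2)
  expect_gt(mean(late), 0.8)
})
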