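# shared fixtures built in code

# ideal 3D Brownian track: n samples at interval dt (min), motility M
brownian_track <- function(n, dt = 1 / 3, M = 60) {
  t <- (seq_len(n) - 1) * dt
  xyz <- apply(matrix(stats::rnorm(3 * (n - 1), sd = sqrt(2 * M * dt)),
                      n - 1, 3), 2, cumsum)
  list(t = t, xyz = rbind(0, xyz))
}

# minimal track table from a list of tracks (each: t, xyz, class)
track_table <- function(tracks, video_id = "v1", experiment_id = "e1") {
  do.call(rbind, lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    data.frame(experiment_id = experiment_id, video_id = video_id,
               track_id = sprintf("t%03d", i),
               cell_class = tr$class %||% "cognate",
               t_min = tr$t, x_um = tr$xyz[, 1], y_um = tr$xyz[, 2],
               z_um = tr$xyz[, 3], stringsAsFactors = FALSE)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# retention points from the exact Gamma CDF (optionally with iid noise on
# the logit scale), for fitting tests
cdf_points <- function(experiment_id, shape, rate, times = seq(1, 10),
                       noise_sd = 0) {
  p <- stats::pgamma(times, shape = shape, rate = rate)
  if (noise_sd > 0)
    p <- stats::plogis(stats::qlogis(pmin(0.99, pmax(0.01, p))) +
                         stats::rnorm(length(p), sd = noise_sd))
  data.frame(experiment_id = experiment_id, time_h = times, fraction = p,
             weight = 1)
}
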