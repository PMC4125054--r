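# Synthetic two-photon-like track sets with known priming ground truth,
# and ready-made circulation scenarios. Cognate cells move as persistent
# random walks until their drawn retention time, then switch to low-motility
# Brownian jitter (arrest); control cells never arrest. Tracks are censored
# to the imaging window with an exponential track-duration model.

#' Specification of a synthetic two-photon experiment set
#'
#' The defaults emulate the structure of the in vivo data the analysis
#' pipeline targets: 6 independent experiments spanning 3 antigen doses
#' (2 experiments per dose), each with 3 one-hour videos imaged at
#' staggered times within 8 h of synchronized LN entry, containing cognate
#' and control cells.
#'
#' The free-cell velocity-jump walk (speed 10 um/min, persistence 1.8 min)
#' has long-time motility v^2 tau / 3 = 60 um^2/min, matching the package
#' default motility coefficient; arrested cells jitter with 5 um^2/min,
#' well below the default gate.
#'
#' @param n_experiments number of experiments.
#' @param doses list of per-dose \code{\link{primingParams}}; experiments
#'   are assigned doses round-robin. The defaults span a low dose (8
#'   required contacts), an intermediate (4) and a high dose (1) at two
#'   effective contacts per hour, placing the low-dose retention switch
#'   near 4 h post entry -- inside the imaged 0--8 h range, as observed
#'   in vivo.
#' @param video_times_h video start times, hours post LN entry.
#' @param cognate_per_video,control_per_video cells per video.
#' @param video_min video length, minutes.
#' @param frame_s frame interval, seconds.
#' @param speed free-cell speed, um/min.
#' @param persistence_min mean persistence time of the walk, minutes.
#' @param arrest_motility motility coefficient of arrested cells, um^2/min.
#' @param track_mean_min mean of the exponential track-duration censoring,
#'   minutes.
#' @return An object of class \code{synthetic_track_spec}.
#' @export
syntheticTrackSpec <- function(
    n_experiments = 6,
    doses = list(low = primingParams(2, 1, 8),
                 mid = primingParams(2, 1, 4),
                 high = primingParams(2, 1, 1)),
    video_times_h = c(1, 4, 7),
    cognate_per_video = 120, control_per_video = 120,
    video_min = 60, frame_s = 20,
    speed = 10, persistence_min = 1.8,
    arrest_motility = 5, track_mean_min = 15) {
  if (n_experiments < 1) stop("need at least one experiment")
  if (!length(doses) || !all(vapply(doses, inherits, logical(1), "priming_params")))
    stop("'doses' must be a list of primingParams()")
  if (any(video_times_h < 0)) stop("video times must be >= 0 (post LN entry)")
  structure(
    list(n_experiments = n_experiments, doses = doses,
         video_times_h = video_times_h,
         cognate_per_video = cognate_per_video,
         control_per_video = control_per_video,
         video_min = video_min, frame_s = frame_s,
         speed = speed, persistence_min = persistence_min,
         arrest_motility = arrest_motility,
         track_mean_min = track_mean_min),
    class = "synthetic_track_spec")
}

# simulate all cells of one video on a common frame grid (frames x cells
# per coordinate), switching each cell from a persistent walk to Brownian
# jitter at its arrest time (minutes from LN entry; Inf for controls).
# Vectorized over cells; the per-frame loop only handles the direction
# persistence and the state switch.
.simVideoTracks <- function(n_frames, frame_min, t_video_min, arrest_min, spec) {
  k <- length(arrest_min)
  x <- matrix(0, n_frames, k); y <- matrix(0, n_frames, k); z <- matrix(0, n_frames, k)
  dirm <- matrix(stats::rnorm(3 * k), 3, k)
  dirm <- sweep(dirm, 2, sqrt(colSums(dirm^2)), "/")
  p_turn <- 1 - exp(-frame_min / spec$persistence_min)
  sd_arrest <- sqrt(2 * spec$arrest_motility * frame_min)
  step_len <- spec$speed * frame_min
  for (j in seq_len(n_frames - 1L)) {
    arrested <- (t_video_min + (j - 1L) * frame_min) >= arrest_min
    turn <- !arrested & (stats::runif(k) < p_turn)
    nt <- sum(turn)
    if (nt) {
      newd <- matrix(stats::rnorm(3 * nt), 3, nt)
      dirm[, turn] <- sweep(newd, 2, sqrt(colSums(newd^2)), "/")
    }
    dx <- ifelse(arrested, stats::rnorm(k, sd = sd_arrest), step_len * dirm[1, ])
    dy <- ifelse(arrested, stats::rnorm(k, sd = sd_arrest), step_len * dirm[2, ])
    dz <- ifelse(arrested, stats::rnorm(k, sd = sd_arrest), step_len * dirm[3, ])
    x[j + 1L, ] <- x[j, ] + dx
    y[j + 1L, ] <- y[j, ] + dy
    z[j + 1L, ] <- z[j, ] + dz
  }
  list(x = x, y = y, z = z)
}

#' Generate a synthetic track set with ground truth
#'
#' Cognate cells draw a retention time from their experiment's dose
#' parameters (clock starting at LN entry) and arrest when it elapses;
#' control cells never arrest. Each cell contributes one track, censored to
#' the video window: the track starts uniformly within the video and lasts
#' an exponential duration (mean \code{track_mean_min}) truncated to the
#' video end. Tracks shorter than 2 min are still emitted; the standard
#' 2-min filter of \code{\link{readTracks}} applies downstream.
#'
#' @param spec a \code{\link{syntheticTrackSpec}}.
#' @return list with \code{tracks} (a \code{\link{trackSet}}) and
#'   \code{ground_truth} (data.frame: experiment_id, video_id, track_id,
#'   cell_class, dose, retention_time_h with NA for controls).
#' @export
generateTrackSet <- function(spec = syntheticTrackSpec()) {
  stopifnot(inherits(spec, "synthetic_track_spec"))
  frame_min <- spec$frame_s / 60
  rows <- list(); gt <- list(); vids <- list()
  dose_names <- names(spec$doses)
  if (is.null(dose_names)) dose_names <- as.character(seq_along(spec$doses))
  for (e in seq_len(spec$n_experiments)) {
    eid <- sprintf("exp%02d", e)
    dose_i <- (e - 1L) %% length(spec$doses) + 1L
    prm <- spec$doses[[dose_i]]
    for (vi in seq_along(spec$video_times_h)) {
      vid <- sprintf("%s_v%d", eid, vi)
      t_video_min <- spec$video_times_h[vi] * 60
      vids[[vid]] <- data.frame(
        video_id = vid, experiment_id = eid,
        time_post_transfer_h = spec$video_times_h[vi] + 1, # +1 h entry offset
        entry_offset_h = 1, duration_min = spec$video_min,
        dose = dose_names[dose_i], stringsAsFactors = FALSE)
      n_cog <- spec$cognate_per_video; n_ctl <- spec$control_per_video
      classes <- c(rep("cognate", n_cog), rep("control", n_ctl))
      arrest <- c(sampleRetentionTime(n_cog, prm) * 60, rep(Inf, n_ctl))
      grid <- seq(0, spec$video_min, by = frame_min)
      paths <- .simVideoTracks(length(grid), frame_min, t_video_min, arrest, spec)
      # censor each cell's path to an observed sub-window of the video
      dur <- pmin(stats::rexp(length(classes), 1 / spec$track_mean_min),
                  spec$video_min)
      start <- stats::runif(length(classes), 0, spec$video_min - dur)
      si <- findInterval(start, grid)
      ei <- pmin(findInterval(start + dur, grid), length(grid))
      keep <- which(ei - si >= 1L)
      if (!length(keep)) next
      idx_list <- lapply(keep, function(ci) si[ci]:ei[ci])
      lens <- lengths(idx_list)
      all_idx <- unlist(idx_list)
      cell_of <- rep(keep, lens)
      tids <- sprintf("%s_c%03d", vid, keep)
      rows[[vid]] <- data.frame(
        experiment_id = eid, video_id = vid,
        track_id = rep(tids, lens),
        cell_class = rep(classes[keep], lens),
        t_min = grid[all_idx],
        x_um = paths$x[cbind(all_idx, cell_of)],
        y_um = paths$y[cbind(all_idx, cell_of)],
        z_um = paths$z[cbind(all_idx, cell_of)],
        stringsAsFactors = FALSE)
      gt[[vid]] <- data.frame(
        experiment_id = eid, video_id = vid, track_id = tids,
        cell_class = classes[keep], dose = dose_names[dose_i],
        retention_time_h = ifelse(is.finite(arrest[keep]),
                                  arrest[keep] / 60, NA_real_),
        stringsAsFactors = FALSE)
    }
  }
  list(tracks = trackSet(do.call(rbind, rows), do.call(rbind, vids)),
       ground_truth = do.call(rbind, gt))
}

#' Ready-made circulation scenarios
#'
#' Named scenario configurations at reduced cohort sizes:
#' \describe{
#'   \item{baseline}{pure surveillance, no dLNs.}
#'   \item{listeria_like}{blood-borne infection: the spleen is the target
#'     organ (arrival analysis, no dLNs).}
#'   \item{influenza_like}{local lung infection draining to 9 single-sphere
#'     dLNs.}
#'   \item{hsv_like}{highly local infection: 2 single-sphere dLNs whose
#'     entry rate ramps 9-fold over the first 4.5 days.}
#'   \item{fig_hypothetical}{hypothetical constant infection in 25\% of the
#'     LN spheres with one cognate DC encounter per hour and 8 required
#'     contacts (capture-time analysis).}
#' }
#'
#' @param name scenario name.
#' @param n_cells cohort size.
#' @param seed RNG seed stored in the scenario.
#' @return list with elements \code{name}, \code{body}, \code{priming}
#'   (or NULL), \code{dln_fraction} (or NA), \code{target},
#'   \code{n_cells}, \code{horizon_h}, \code{seed}.
#' @export
circulationFixture <- function(name = c("baseline", "listeria_like",
                                        "influenza_like", "hsv_like",
                                        "fig_hypothetical"),
                               n_cells = 2000, seed = 1) {
  name <- match.arg(name)
  base <- list(name = name, n_cells = n_cells, seed = seed,
               priming = NULL, dln_fraction = NA_real_)
  switch(name,
    baseline = c(base, list(body = bodyConfig(), target = "ln",
                            horizon_h = 336)),
    listeria_like = c(base, list(body = bodyConfig(), target = "spleen",
                                 horizon_h = 120)),
    influenza_like = c(base, list(body = bodyConfig(dln_count = 9),
                                  target = "dln", horizon_h = 120)),
    hsv_like = c(base, list(body = bodyConfig(dln_count = 2,
                                              ramp = entryRateRamp(9, 4.5)),
                            target = "dln", horizon_h = 240)),
    fig_hypothetical = {
      base$priming <- primingParams(1, 1, 8)
      base$dln_fraction <- 0.25
      c(base, list(body = bodyConfig(), target = "dln", horizon_h = 2000))
    })
}
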