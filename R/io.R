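# Readers/writers for the delimited track, metadata and trajectory tables,
# and structured-text (YAML) scenario configurations. All time columns
# carry their unit in the column name: minutes for imaging tables, hours
# for circulation tables.

#' Read and write track tables
#'
#' Track tables are comma-separated with the documented header
#' (\code{experiment_id, video_id, track_id, cell_class, t_min, x_um,
#' y_um, z_um}); video metadata is a companion table (\code{video_id,
#' experiment_id, time_post_transfer_h, entry_offset_h, duration_min},
#' optional \code{dose}). On reading, tracks shorter than 2 minutes are
#' removed (with a message reporting the count), and non-monotone
#' timestamps within a track are a hard error.
#'
#' @param path track table path.
#' @param videos_path video metadata path; defaults to
#'   \code{<path-without-ext>_videos.csv}.
#' @param min_duration_min minimum track duration (default 2 min).
#' @return a \code{\link{trackSet}}.
#' @export
readTracks <- function(path, videos_path = NULL, min_duration_min = 2) {
  if (is.null(videos_path))
    videos_path <- paste0(sub("\\.[^.]+$", "", path), "_videos.csv")
  tracks <- utils::read.csv(path, stringsAsFactors = FALSE)
  videos <- utils::read.csv(videos_path, stringsAsFactors = FALSE)
  key <- interaction(tracks$video_id, tracks$track_id, drop = TRUE)
  dur <- tapply(tracks$t_min, key, function(x) diff(range(x)))
  short <- names(dur)[dur < min_duration_min]
  if (length(short)) {
    message(sprintf("removed %d track(s) shorter than %g min", length(short),
                    min_duration_min))
    tracks <- tracks[!(key %in% short), , drop = FALSE]
  }
  if (!nrow(tracks)) stop("no tracks left after the duration filter")
  trackSet(tracks, videos)
}

#' @rdname readTracks
#' @param ts a \code{\link{trackSet}} to write.
#' @export
writeTracks <- function(ts, path, videos_path = NULL) {
  stopifnot(inherits(ts, "track_set"))
  if (is.null(videos_path))
    videos_path <- paste0(sub("\\.[^.]+$", "", path), "_videos.csv")
  utils::write.csv(ts$tracks, path, row.names = FALSE, quote = FALSE)
  utils::write.csv(ts$videos, videos_path, row.names = FALSE, quote = FALSE)
  invisible(c(path, videos_path))
}

#' Write a cohort's episode table
#'
#' Long-format trajectory table: \code{cell_id, compartment, t_entry_h,
#' t_exit_h, outcome}, with compartments labeled \code{blood},
#' \code{spleen}, \code{ln_<i>}.
#'
#' @param cohort a \code{cohort_sim} with episodes.
#' @param path output path.
#' @export
writeTrajectories <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_sim"))
  ep <- cohort$episodes
  if (is.null(ep)) stop("cohort was simulated with record = FALSE")
  lab <- ifelse(ep$compartment == 0L, "blood",
                ifelse(ep$compartment == 1L, "spleen",
                       sprintf("ln_%02d", ep$compartment - 1L)))
  out <- data.frame(cell_id = ep$cell_id, compartment = lab,
                    t_entry_h = ep$t_entry_h, t_exit_h = ep$t_exit_h,
                    outcome = c("circulating", "retained")[cohort$outcome[ep$cell_id] + 1L])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write scenario configurations
#'
#' Scenario configs are YAML documents with sections \code{body}
#' (entry rates, dLN designation, optional ramp), \code{geometry} (LN
#' sphere and spleen section), optional \code{priming}
#' (\code{contact_rate_per_h}, \code{success_prob},
#' \code{required_contacts}), and run settings (\code{n_cells},
#' \code{horizon_h}, \code{seed}; the seed is mandatory for stochastic
#' runs).
#'
#' @param path YAML file path.
#' @return \code{readScenario}: list with \code{body}
#'   (\code{\link{bodyConfig}}), \code{priming}
#'   (\code{\link{primingParams}} or NULL), \code{dln_fraction},
#'   \code{n_cells}, \code{horizon_h}, \code{seed}, \code{name}.
#' @export
readScenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  geom <- cfg$geometry
  ln_geom <- if (is.null(geom$ln)) lnSphere() else
    lnSphere(radius = geom$ln$radius_um %||% 540,
             motility = geom$ln$motility_um2_min %||% 60)
  sp_geom <- if (is.null(geom$spleen)) spleenSection() else
    spleenSection(radius = geom$spleen$radius_um %||% 120,
                  aperture = geom$spleen$aperture_rad %||% .SPLEEN_DEFAULT_APERTURE,
                  motility = geom$spleen$motility_um2_min %||% 60)
  b <- cfg$body
  ramp <- if (!is.null(b$ramp))
    entryRateRamp(fold = b$ramp$fold %||% 9,
                  ramp_end_days = b$ramp$ramp_end_days %||% 4.5,
                  shape = b$ramp$shape %||% "linear")
  body <- bodyConfig(
    spleen_entry_rate = b$spleen_entry_rate_per_h %||% 1.0,
    ln_entry_total = b$ln_entry_total_per_h %||% 1.5,
    dln_count = b$dln_count %||% 0,
    ramp = ramp, ln_geom = ln_geom, spleen_geom = sp_geom)
  priming <- if (!is.null(cfg$priming))
    primingParams(contact_rate = cfg$priming$contact_rate_per_h %||% 1,
                  success_prob = cfg$priming$success_prob %||% 1,
                  required_contacts = cfg$priming$required_contacts %||% 1)
  list(name = cfg$name %||% "scenario", body = body, priming = priming,
       dln_fraction = cfg$dln_fraction %||% NA_real_,
       n_cells = cfg$n_cells %||% 1000,
       horizon_h = cfg$horizon_h %||% 336,
       seed = cfg$seed)
}

#' @rdname readScenario
#' @param scenario a scenario list as returned by \code{readScenario} or
#'   \code{\link{circulationFixture}}.
#' @export
writeScenario <- function(scenario, path) {
  body <- scenario$body
  cfg <- list(
    name = scenario$name,
    body = list(
      spleen_entry_rate_per_h = body$spleen_entry_rate,
      ln_entry_total_per_h = sum(body$ln_entry_rates),
      dln_count = length(body$dln_spheres)),
    geometry = list(
      ln = list(radius_um = body$ln_geom$radius,
                motility_um2_min = body$ln_geom$motility),
      spleen = list(radius_um = body$spleen_geom$radius,
                    aperture_rad = body$spleen_geom$aperture,
                    motility_um2_min = body$spleen_geom$motility)),
    n_cells = scenario$n_cells,
    horizon_h = scenario$horizon_h,
    seed = scenario$seed)
  if (!is.null(body$ramp))
    cfg$body$ramp <- list(fold = body$ramp$fold,
                          ramp_end_days = body$ramp$ramp_end_h / 24,
                          shape = body$ramp$shape)
  if (!is.null(scenario$priming))
    cfg$priming <- list(
      contact_rate_per_h = scenario$priming$contact_rate,
      success_prob = scenario$priming$success_prob,
      required_contacts = scenario$priming$required_contacts)
  if (!is.na(scenario$dln_fraction %||% NA_real_))
    cfg$dln_fraction <- scenario$dln_fraction
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
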