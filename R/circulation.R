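# Kinetic Monte Carlo circulation of single T cells between blood, spleen
# and 39 LN spheres. Cells in the blood exit at total rate
# Lambda(t) = sigma_spleen + sum_i sigma_i(t); the destination organ is
# chosen with probability rate/Lambda. Organ dwell times come from the
# first-passage transit laws (or a fixed dwell for deterministic LN transit).

# default mapping of 30 named LNs onto 39 spheres: the six large paired
# peripheral LNs (axillary, brachial, inguinal; left/right) get 2 spheres
# each, the mesenteric LN gets 4, the remaining 23 LNs 1 each
.defaultSphereMap <- function() {
  paired <- c("axillary_L", "axillary_R", "brachial_L", "brachial_R",
              "inguinal_L", "inguinal_R")
  others <- c("popliteal_L", "popliteal_R",
              sprintf("ln_%02d", seq_len(21)))
  data.frame(
    ln_name = c(paired, "mesenteric", others),
    n_spheres = c(rep(2L, 6L), 4L, rep(1L, 23L)),
    stringsAsFactors = FALSE)
}

#' Entry-rate ramp for draining lymph nodes
#'
#' After a local infection, inflammation-driven vascular growth increases
#' cell influx into the draining LNs. The default emulates the measured
#' ~9-fold increase over the first 4.5 days post infection.
#'
#' @param fold fold increase of the dLN entry rate (>= 1).
#' @param ramp_end_days time at which the full fold increase is reached,
#'   days post infection.
#' @param shape \code{"linear"}: rate rises linearly from 1x at t = 0 to
#'   \code{fold}x at \code{ramp_end_days}, constant after; \code{"step"}:
#'   jumps to \code{fold}x at t = 0.
#' @return An object of class \code{entry_rate_ramp}.
#' @export
entryRateRamp <- function(fold = 9, ramp_end_days = 4.5,
                          shape = c("linear", "step")) {
  shape <- match.arg(shape)
  if (!is.numeric(fold) || length(fold) != 1L || fold < 1)
    stop("'fold' must be >= 1")
  if (shape == "linear" && (!is.numeric(ramp_end_days) || ramp_end_days <= 0))
    stop("'ramp_end_days' must be positive for a linear ramp")
  structure(list(fold = fold,
                 ramp_end_h = if (shape == "step") 0 else ramp_end_days * 24,
                 shape = shape),
            class = "entry_rate_ramp")
}

#' Body configuration for the circulation model
#'
#' Defines the compartment graph: blood, one spleen and 39 LN spheres with
#' per-sphere entry rates, plus the transit geometries. The default entry
#' rates (spleen 1.0/h, all LNs combined 1.5/h split evenly over the
#' spheres) reproduce the classical blood residence time of ~25 min and the
#' steady-state T cell distribution of roughly 74\% LN / 23\% spleen / 3\%
#' blood when combined with the default 13.5 h LN and 6 h spleen mean
#' transits.
#'
#' @param spleen_entry_rate blood-to-spleen entry rate, per hour.
#' @param ln_entry_total combined blood-to-LN entry rate over all spheres,
#'   per hour (split evenly).
#' @param dln_count number of single-sphere LNs designated as draining
#'   (ignored if \code{dln_spheres} is given).
#' @param dln_spheres integer indices (1..39) of draining spheres.
#' @param ramp optional \code{\link{entryRateRamp}} applied to the dLN
#'   entry rates from t = 0 (infection) on.
#' @param ln_geom an \code{\link{lnSphere}} shared by all spheres.
#' @param spleen_geom a \code{\link{spleenSection}}.
#' @param sphere_map data.frame mapping named LNs to sphere counts; the
#'   default maps 30 LNs to 39 spheres.
#' @return An object of class \code{body_config}.
#' @export
bodyConfig <- function(spleen_entry_rate = 1.0, ln_entry_total = 1.5,
                       dln_count = 0, dln_spheres = NULL, ramp = NULL,
                       ln_geom = lnSphere(), spleen_geom = spleenSection(),
                       sphere_map = .defaultSphereMap()) {
  if (spleen_entry_rate <= 0 || ln_entry_total <= 0)
    stop("entry rates must be positive")
  n_spheres <- sum(sphere_map$n_spheres)
  sphere_ln <- rep(sphere_map$ln_name, sphere_map$n_spheres)
  if (is.null(dln_spheres)) {
    if (dln_count > 0) {
      # by convention dLN counts refer to LNs represented by a single sphere
      singles <- which(sphere_ln %in% sphere_map$ln_name[sphere_map$n_spheres == 1L])
      if (dln_count > length(singles))
        stop("not enough single-sphere LNs for 'dln_count'")
      dln_spheres <- singles[seq_len(dln_count)]
    } else dln_spheres <- integer(0)
  }
  if (length(dln_spheres) && (any(dln_spheres < 1) || any(dln_spheres > n_spheres)))
    stop("'dln_spheres' out of range")
  if (!is.null(ramp) && !inherits(ramp, "entry_rate_ramp"))
    stop("'ramp' must be an entryRateRamp()")
  structure(
    list(spleen_entry_rate = spleen_entry_rate,
         ln_entry_rates = rep(ln_entry_total / n_spheres, n_spheres),
         sphere_ln = sphere_ln,
         dln_spheres = as.integer(dln_spheres),
         ramp = ramp,
         ln_geom = ln_geom,
         spleen_geom = spleen_geom),
    class = "body_config")
}

#' @export
print.body_config <- function(x, ...) {
  cat(sprintf(
    "Body: spleen entry %.3g /h, %d LN spheres (total entry %.3g /h), %d dLN sphere(s)%s\n",
    x$spleen_entry_rate, length(x$ln_entry_rates), sum(x$ln_entry_rates),
    length(x$dln_spheres),
    if (is.null(x$ramp)) "" else sprintf(", ramp %gx by %g h", x$ramp$fold, x$ramp$ramp_end_h)))
  invisible(x)
}

#' Total blood exit rate
#'
#' \eqn{\Lambda(t)}, the sum of all organ entry rates at time t (hours post
#' infection); the mean blood sojourn is \eqn{1/\Lambda}.
#'
#' @param body a \code{\link{bodyConfig}}.
#' @param t time in hours (vectorized; t < 0 is pre-infection baseline).
#' @return rate per hour.
#' @export
bloodExitRate <- function(body, t = 0) {
  stopifnot(inherits(body, "body_config"))
  base <- body$spleen_entry_rate + sum(body$ln_entry_rates)
  if (is.null(body$ramp) || !length(body$dln_spheres)) return(rep(base, length(t)))
  dln_total <- sum(body$ln_entry_rates[body$dln_spheres])
  fold <- .rampFold(body$ramp, t)
  base + (fold - 1) * dln_total
}

.rampFold <- function(ramp, t) {
  if (is.null(ramp)) return(rep(1, length(t)))
  ifelse(t <= 0, 1,
         ifelse(t >= ramp$ramp_end_h, ramp$fold,
                1 + (ramp$fold - 1) * t / max(ramp$ramp_end_h, .Machine$double.eps)))
}

#' One blood sojourn
#'
#' Draws the blood dwell time (exponential with rate \eqn{\Lambda(t)},
#' time-varying rates handled by thinning) and the next organ (chosen with
#' probability rate/\eqn{\Lambda}).
#'
#' @param body a \code{\link{bodyConfig}}.
#' @param t time of blood entry, hours.
#' @return list with \code{organ} (\code{"spleen"} or \code{"ln"}),
#'   \code{sphere} (index or NA), \code{dwell_h}.
#' @export
stepBlood <- function(body, t = 0) {
  stopifnot(inherits(body, "body_config"))
  lambda_max <- max(bloodExitRate(body, c(t, 1e6)))
  t_exit <- t
  repeat {
    t_exit <- t_exit + stats::rexp(1, lambda_max)
    if (stats::runif(1) <= bloodExitRate(body, t_exit) / lambda_max) break
  }
  fold <- .rampFold(body$ramp, t_exit)
  rates <- body$ln_entry_rates
  if (length(body$dln_spheres))
    rates[body$dln_spheres] <- rates[body$dln_spheres] * fold
  all_rates <- c(body$spleen_entry_rate, rates)
  pick <- sample.int(length(all_rates), 1L, prob = all_rates)
  if (pick == 1L)
    list(organ = "spleen", sphere = NA_integer_, dwell_h = t_exit - t)
  else
    list(organ = "ln", sphere = pick - 1L, dwell_h = t_exit - t)
}

#' Transit mode for LN dwell times
#'
#' @param kind \code{"stochastic"}: sample each LN dwell from the sphere
#'   first-passage law; \code{"deterministic"}: fixed dwell \code{T_det}.
#'   Spleen transit is always stochastic.
#' @param T_det fixed LN dwell in hours (deterministic mode only).
#' @return An object of class \code{transit_mode}.
#' @export
transitMode <- function(kind = c("stochastic", "deterministic"), T_det = NULL) {
  kind <- match.arg(kind)
  if (kind == "deterministic") {
    if (is.null(T_det) || !is.numeric(T_det) || length(T_det) != 1L || T_det <= 0)
      stop("'T_det' must be a single positive number of hours")
  } else T_det <- NA_real_
  structure(list(kind = kind, T_det = T_det), class = "transit_mode")
}

# shared driver for all cohort simulations
.runCohort <- function(n_cells, body, horizon, mode, priming, burn_in,
                       dln_visit_prob, record) {
  stopifnot(inherits(body, "body_config"))
  if (!inherits(mode, "transit_mode")) stop("'mode' must be a transitMode()")
  if (!is.null(priming) && !inherits(priming, "priming_params"))
    stop("'priming' must be a primingParams() or NULL")
  if (horizon <= 0) stop("'horizon' must be positive")
  if (dln_visit_prob >= 0 && !is.null(body$ramp))
    stop("a dLN visit fraction cannot be combined with an entry-rate ramp")
  burn <- if (isTRUE(burn_in)) (1 + stats::runif(n_cells)) * 168 else rep(0, n_cells)
  dln_flag <- integer(length(body$ln_entry_rates))
  dln_flag[body$dln_spheres] <- 1L
  ln_tab <- .lnQuantileTable(body$ln_geom)
  sp_tab <- .spleenQuantileTable(body$spleen_geom)
  ramp_fold <- if (is.null(body$ramp)) 1 else body$ramp$fold
  ramp_end <- if (is.null(body$ramp)) 0 else body$ramp$ramp_end_h
  res <- cpp_simulate_cohort(
    as.integer(n_cells), burn, horizon,
    body$spleen_entry_rate, body$ln_entry_rates, dln_flag,
    ramp_fold, ramp_end,
    if (mode$kind == "deterministic") mode$T_det else -1,
    ln_tab$F, ln_tab$t, sp_tab$F, sp_tab$t,
    if (is.null(priming)) -1 else priming$required_contacts,
    if (is.null(priming)) -1 else successRate(priming),
    dln_visit_prob, record)
  structure(
    list(episodes = if (record) res$episodes else NULL,
         outcome = res$outcome,
         retention_time = res$retention_time,
         initial_dln = res$initial_dln == 1L,
         n_cells = n_cells, horizon = horizon, body = body,
         mode = mode, priming = priming, burn_in = burn_in),
    class = "cohort_sim")
}

#' Simulate a cohort of circulating T cells
#'
#' Runs the kinetic Monte Carlo circulation for \code{n_cells} independent
#' cells from t = 0 (infection / observation start) to \code{horizon}. With
#' \code{burn_in = TRUE} each cell is first circulated for 1 + u weeks
#' (u uniform) before t = 0, which desynchronizes the cohort and puts it in
#' the stationary occupancy distribution; with \code{burn_in = FALSE} all
#' cells start in the blood at t = 0.
#'
#' If \code{priming} is given, every visit to a draining sphere draws a
#' retention time A from the priming law, and the cell is retained (the
#' trajectory terminates) if A is shorter than the remaining dwell; antigen
#' appears at t = 0, so for a cell already inside a dLN at that moment
#' priming runs over the part of its dwell after t = 0.
#'
#' @param n_cells cohort size.
#' @param body a \code{\link{bodyConfig}}.
#' @param horizon simulated hours after t = 0.
#' @param mode a \code{\link{transitMode}}.
#' @param priming optional \code{\link{primingParams}} enabling retention in
#'   dLN spheres.
#' @param burn_in logical, see above.
#' @param record keep the full episode table (set \code{FALSE} for large
#'   capture runs where only outcomes are needed).
#' @return An object of class \code{cohort_sim} with elements
#'   \code{episodes} (data.frame: cell_id, compartment code 0 = blood,
#'   1 = spleen, 2.. = LN sphere + 2, t_entry_h, t_exit_h), \code{outcome},
#'   \code{retention_time}, \code{initial_dln}.
#' @export
simulateCohort <- function(n_cells, body = bodyConfig(), horizon = 336,
                           mode = transitMode(), priming = NULL,
                           burn_in = TRUE, record = TRUE) {
  .runCohort(n_cells, body, horizon, mode, priming, burn_in,
             dln_visit_prob = -1, record = record)
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("Cohort simulation: %d cells, horizon %g h, %s LN transit%s\n",
              x$n_cells, x$horizon, x$mode$kind,
              if (is.null(x$priming)) "" else
                sprintf(", %d retained", sum(x$outcome == 1L))))
  invisible(x)
}

#' Time-averaged compartment occupancy
#'
#' Fraction of cell-time spent in blood, spleen and LNs over a time window,
#' computed from the episode table.
#'
#' @param cohort a \code{cohort_sim} simulated with \code{record = TRUE}.
#' @param from,to window in hours (defaults: 0 to the horizon).
#' @return named numeric vector (blood, spleen, ln) summing to 1.
#' @export
occupancyFractions <- function(cohort, from = 0, to = cohort$horizon) {
  stopifnot(inherits(cohort, "cohort_sim"))
  ep <- cohort$episodes
  if (is.null(ep)) stop("cohort was simulated with record = FALSE")
  ov <- pmin(ep$t_exit_h, to) - pmax(ep$t_entry_h, from)
  ov[ov < 0] <- 0
  cls <- ifelse(ep$compartment == 0L, "blood",
                ifelse(ep$compartment == 1L, "spleen", "ln"))
  tot <- tapply(ov, cls, sum)
  out <- c(blood = 0, spleen = 0, ln = 0)
  out[names(tot)] <- tot
  out / sum(out)
}

#' Compartment occupancy at a time point
#'
#' @param cohort a \code{cohort_sim} with episodes.
#' @param at time in hours.
#' @return named fractions of cells in blood / spleen / ln at \code{at}.
#' @export
occupancyAt <- function(cohort, at = 0) {
  stopifnot(inherits(cohort, "cohort_sim"))
  ep <- cohort$episodes
  if (is.null(ep)) stop("cohort was simulated with record = FALSE")
  sel <- ep$t_entry_h <= at & ep$t_exit_h > at
  cls <- ifelse(ep$compartment[sel] == 0L, "blood",
                ifelse(ep$compartment[sel] == 1L, "spleen", "ln"))
  tab <- table(factor(cls, levels = c("blood", "spleen", "ln")))
  out <- as.numeric(tab) / sum(tab)
  names(out) <- c("blood", "spleen", "ln")
  out
}

#' First arrival times at a set of target compartments
#'
#' Returns, per cell, the first time at or after t = 0 at which the cell is
#' inside any target compartment. By the default convention a cell already
#' inside a target at t = 0 gets arrival time 0; with
#' \code{include_initial = FALSE} such cells instead count their next entry
#' into a target.
#'
#' @param cohort a \code{cohort_sim} with episodes.
#' @param target \code{"spleen"}, \code{"blood"}, \code{"ln"} (any LN
#'   sphere), \code{"dln"} (the body's draining spheres), or an integer
#'   vector of sphere indices (1..39).
#' @param include_initial logical, see above.
#' @return numeric vector of arrival times in hours (NA if the cell never
#'   reaches a target before the horizon).
#' @export
arrivalTimes <- function(cohort, target = "spleen", include_initial = TRUE) {
  stopifnot(inherits(cohort, "cohort_sim"))
  ep <- cohort$episodes
  if (is.null(ep)) stop("cohort was simulated with record = FALSE")
  if (is.character(target)) {
    target <- match.arg(target, c("spleen", "blood", "ln", "dln"))
    comp_ok <- switch(target,
      blood = ep$compartment == 0L,
      spleen = ep$compartment == 1L,
      ln = ep$compartment >= 2L,
      dln = {
        if (!length(cohort$body$dln_spheres)) stop("body has no dLN spheres")
        ep$compartment %in% (cohort$body$dln_spheres + 1L)
      })
  } else {
    if (!length(target)) stop("empty target set")
    comp_ok <- ep$compartment %in% (as.integer(target) + 1L)
  }
  sel <- comp_ok & ep$t_exit_h > 0
  tt <- pmax(ep$t_entry_h[sel], 0)
  if (!include_initial) {
    keep <- ep$t_entry_h[sel] >= 0
    tt <- tt[keep]
    cells <- ep$cell_id[sel][keep]
  } else cells <- ep$cell_id[sel]
  out <- rep(NA_real_, cohort$n_cells)
  if (length(tt)) {
    first <- tapply(tt, cells, min)
    out[as.integer(names(first))] <- as.numeric(first)
  }
  out
}

#' Depletion of cells from non-draining tissue
#'
#' Timecourse of the fraction of cells that are outside the draining LNs:
#' not yet retained and not currently inside a dLN sphere. With an
#' entry-rate ramp the depletion is faster than without.
#'
#' @param cohort a \code{cohort_sim} with episodes, simulated with priming
#'   and a nonempty dLN set (a body with 0 dLNs yields a flat curve at 1).
#' @param times evaluation times in hours.
#' @return data.frame with \code{time_h} and \code{fraction_outside}.
#' @export
ndlnDepletionCurve <- function(cohort, times = seq(0, cohort$horizon, by = 4)) {
  stopifnot(inherits(cohort, "cohort_sim"))
  ep <- cohort$episodes
  if (is.null(ep)) stop("cohort was simulated with record = FALSE")
  dln_comp <- cohort$body$dln_spheres + 1L
  in_dln <- ep$compartment %in% dln_comp
  ret <- cohort$retention_time
  frac <- vapply(times, function(tt) {
    retained <- !is.na(ret) & ret <= tt
    sel <- in_dln & ep$t_entry_h <= tt & ep$t_exit_h > tt
    inside <- unique(ep$cell_id[sel])
    1 - (sum(retained) + length(setdiff(inside, which(retained)))) / cohort$n_cells
  }, numeric(1))
  data.frame(time_h = times, fraction_outside = frac)
}
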