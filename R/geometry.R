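# Within-organ transit models.
#
# The LN T cell zone is a sphere of radius R (um) that cells enter at the
# centre (the HEV) and leave on first contact with the absorbing surface
# (sinusoids); motion is Brownian with motility coefficient M (um^2/min,
# 3D MSD = 6 M t). The splenic PALS is a cylinder whose axial coordinate is
# irrelevant, so transit is modeled in the 2D cross-section: a disc of
# radius R_S entered at a boundary point, with a reflecting boundary except
# an absorbing arc (aperture angle alpha) diametrically opposite the entry.

# minutes -> hours conversion for motility: um^2/min to um^2/h
.M_PER_H <- 60

# default spleen aperture, calibrated with calibrateSpleen() to a 6 h mean
# transit at radius 120 um, M = 60 um^2/min, dt = 0.2 min (2e4 transits per
# evaluation; achieved mean 6.0 h, reproducible across seeds within ~1.5%)
.SPLEEN_DEFAULT_APERTURE <- 1.865

#' Lymph-node sphere geometry
#'
#' @param radius sphere radius in micrometres. The default (540 um) is
#'   calibrated so that with the default motility the mean transit time is
#'   13.5 h (see \code{\link{calibrateLnRadius}}).
#' @param motility motility coefficient in um^2/min (3D MSD = 6 M t).
#'   Only the ratio radius^2 / motility affects transit dynamics; 60 um^2/min
#'   is the two-photon scale estimate used as the package convention.
#' @return An object of class \code{ln_sphere}.
#' @export
lnSphere <- function(radius = 540, motility = 60) {
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("'radius' must be a single positive number (um)")
  if (!is.numeric(motility) || length(motility) != 1L || motility <= 0)
    stop("'motility' must be a single positive number (um^2/min)")
  structure(list(radius = radius, motility = motility), class = "ln_sphere")
}

#' @export
print.ln_sphere <- function(x, ...) {
  cat(sprintf("LN sphere: R = %g um, M = %g um^2/min (mean transit %.3g h)\n",
              x$radius, x$motility, lnMeanTransit(x)))
  invisible(x)
}

#' Mean LN transit time
#'
#' The mean first-passage time of Brownian motion from the centre of an
#' absorbing sphere, \eqn{R^2 / (6M)}, converted to hours.
#'
#' @param geom an \code{\link{lnSphere}}.
#' @return mean transit time in hours.
#' @export
lnMeanTransit <- function(geom) {
  stopifnot(inherits(geom, "ln_sphere"))
  geom$radius^2 / (6 * geom$motility * .M_PER_H)
}

#' Calibrate the LN sphere radius to a target mean transit time
#'
#' Inverts the mean first-passage law: \eqn{R = \sqrt{6 M t}}.
#'
#' @param target_mean target mean transit time, hours.
#' @param motility motility coefficient, um^2/min.
#' @return radius in micrometres.
#' @export
calibrateLnRadius <- function(target_mean, motility = 60) {
  if (!is.numeric(target_mean) || length(target_mean) != 1L || target_mean <= 0)
    stop("'target_mean' must be a single positive number of hours")
  sqrt(6 * motility * .M_PER_H * target_mean)
}

# survival S(tau) at dimensionless time tau = M t / R^2 via the alternating
# eigen-series 2 * sum_k (-1)^(k+1) exp(-k^2 pi^2 tau); for tau < 1e-5 the
# true survival is 1 to far beyond machine precision
.sphereSurvivalTau <- function(tau) {
  out <- numeric(length(tau))
  for (i in seq_along(tau)) {
    if (tau[i] < 1e-5) { out[i] <- 1; next }
    s <- 0
    for (k in 1:2000) {
      term <- exp(-k^2 * pi^2 * tau[i])
      s <- s + if (k %% 2L == 1L) term else -term
      if (term < 1e-12) break
    }
    out[i] <- min(1, max(0, 2 * s))
  }
  out
}

#' LN transit-time survival function
#'
#' P(T > t) for the first-passage time of Brownian motion from the centre of
#' the absorbing sphere, via the exact alternating exponential eigen-series.
#' The series is truncated once terms drop below 1e-12 (at most 2000 terms);
#' for dimensionless times \eqn{M t / R^2 < 10^{-5}} the survival is returned
#' as exactly 1.
#'
#' @param t time in hours (vectorized, >= 0).
#' @param geom an \code{\link{lnSphere}}.
#' @return survival probabilities in [0, 1].
#' @export
lnSurvival <- function(t, geom) {
  stopifnot(inherits(geom, "ln_sphere"))
  if (any(!is.finite(t) | t < 0)) stop("'t' must be finite and >= 0")
  tau <- geom$motility * .M_PER_H * t / geom$radius^2
  .sphereSurvivalTau(tau)
}

# tabulated CDF of the dimensionless transit time, used for inverse-CDF
# sampling (shared by R and C++ callers); beyond tau = 4 the survival is
# ~1e-17 so clamping at the last knot is exact for all practical purposes
.lnTauTable <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      tau <- c(0, exp(seq(log(2e-3), log(4), length.out = 1500)))
      F <- 1 - .sphereSurvivalTau(tau)
      keep <- !duplicated(F)
      tab <<- list(tau = tau[keep], F = F[keep])
    }
    tab
  }
})

# CDF table in hours for a given geometry (list(F, t))
.lnQuantileTable <- function(geom) {
  tab <- .lnTauTable()
  list(F = tab$F, t = tab$tau * geom$radius^2 / (geom$motility * .M_PER_H))
}

#' Sample LN transit times
#'
#' \code{sampleLnTransit} draws first-passage times by inverse-CDF sampling
#' on the analytic eigen-series (the production sampler used inside the
#' circulation simulator). \code{sampleLnTransitBrownian} instead simulates
#' explicit discretized Brownian walks in the sphere and is kept as an
#' independent oracle.
#'
#' @param n number of samples.
#' @param geom an \code{\link{lnSphere}}.
#' @return transit times in hours.
#' @export
sampleLnTransit <- function(n, geom) {
  stopifnot(inherits(geom, "ln_sphere"))
  tab <- .lnQuantileTable(geom)
  stats::approx(tab$F, tab$t, xout = stats::runif(n), rule = 2)$y
}

#' @rdname sampleLnTransit
#' @param dt Brownian step size in minutes (per-axis step sd
#'   \code{sqrt(2 M dt)}).
#' @export
sampleLnTransitBrownian <- function(n, geom, dt = 0.1) {
  stopifnot(inherits(geom, "ln_sphere"))
  if (dt <= 0) stop("'dt' must be positive")
  cpp_sphere_fpt(n, geom$radius, geom$motility, dt)
}

#' Laplace transform of the LN transit time
#'
#' \eqn{E[e^{-sT}] = z / \sinh(z)} with \eqn{z = R \sqrt{s / M}} (unit
#' consistent: s per hour, M converted to um^2/h). Equals 1 at s = 0. This
#' is also the building block of the closed-form retention probability for
#' probabilistic priming.
#'
#' @param s transform variable, per hour (vectorized, >= 0).
#' @param geom an \code{\link{lnSphere}}.
#' @return values in (0, 1].
#' @export
lnTransitLaplace <- function(s, geom) {
  stopifnot(inherits(geom, "ln_sphere"))
  if (any(!is.finite(s) | s < 0)) stop("'s' must be finite and >= 0")
  z <- geom$radius * sqrt(s / (geom$motility * .M_PER_H))
  out <- ifelse(z < 1e-8, 1, 2 * z * exp(-z) / (1 - exp(-2 * z)))
  pmin(1, out)
}

#' Spleen cross-section geometry
#'
#' @param radius disc radius of the PALS cross-section, micrometres.
#' @param aperture absorbing aperture angle alpha in radians, centred
#'   diametrically opposite the entry point; must lie in (0, pi). The
#'   default is calibrated so that the mean transit time is 6 h at the
#'   default radius and motility (see \code{\link{calibrateSpleen}} and the
#'   methods vignette for the calibration record).
#' @param motility motility coefficient, um^2/min (in-plane MSD = 4 M t).
#' @return An object of class \code{spleen_section}.
#' @export
spleenSection <- function(radius = 120, aperture = .SPLEEN_DEFAULT_APERTURE,
                          motility = 60) {
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("'radius' must be a single positive number (um)")
  if (!is.numeric(aperture) || length(aperture) != 1L ||
      aperture <= 0 || aperture >= pi)
    stop("'aperture' must be in (0, pi) radians")
  if (!is.numeric(motility) || length(motility) != 1L || motility <= 0)
    stop("'motility' must be a single positive number (um^2/min)")
  structure(list(radius = radius, aperture = aperture, motility = motility),
            class = "spleen_section")
}

#' @export
print.spleen_section <- function(x, ...) {
  cat(sprintf("Spleen cross-section: R = %g um, aperture = %.3g rad, M = %g um^2/min\n",
              x$radius, x$aperture, x$motility))
  invisible(x)
}

#' Simulate spleen transit times
#'
#' Explicit 2D Brownian motion in the disc: entry exactly on the boundary,
#' specular (radial) reflection back into the disc on boundary crossings,
#' absorption on the aperture arc. The step size must satisfy
#' \code{sqrt(4 M dt) < radius / 10} so that per-step displacements stay
#' small relative to the geometry.
#'
#' @param n number of transits.
#' @param geom a \code{\link{spleenSection}}.
#' @param dt time step in minutes.
#' @return transit times in hours.
#' @export
sampleSpleenTransit <- function(n, geom, dt = 0.2) {
  stopifnot(inherits(geom, "spleen_section"))
  if (dt <= 0) stop("'dt' must be positive")
  if (sqrt(4 * geom$motility * dt) >= geom$radius / 10)
    stop(sprintf(
      "step size too coarse: need sqrt(4 M dt) < radius/10, i.e. dt < %.3g min",
      (geom$radius / 10)^2 / (4 * geom$motility)))
  cpp_disc_transit(n, geom$radius, geom$aperture, geom$motility, dt)
}

# empirical transit-time CDF table for the circulation simulator, built from
# one batch of explicit disc walks on an isolated RNG stream (so that the
# memoized table never perturbs the caller's random stream)
.spleen_cache <- new.env(parent = emptyenv())

.spleenQuantileTable <- function(geom, n = 20000, dt = 0.2) {
  key <- paste(signif(geom$radius, 10), signif(geom$aperture, 10),
               signif(geom$motility, 10), n, dt, sep = "|")
  if (!is.null(.spleen_cache[[key]])) return(.spleen_cache[[key]])
  seed_old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(seed_old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", seed_old, envir = globalenv())
  })
  set.seed(20140807L) # fixed internal stream, table is deterministic per geometry
  draws <- sort(sampleSpleenTransit(n, geom, dt))
  tab <- list(F = (seq_len(n) - 0.5) / n, t = draws)
  .spleen_cache[[key]] <- tab
  tab
}

#' Calibrate the spleen aperture angle to a target mean transit time
#'
#' Numerically solves for the aperture angle alpha such that the Monte Carlo
#' mean transit time matches \code{target_mean}. The mean is monotone
#' decreasing in alpha, so the solver bisects on a bracket; each evaluation
#' uses \code{n_eval} explicit transits.
#'
#' @param target_mean target mean transit time, hours.
#' @param motility motility coefficient, um^2/min.
#' @param radius disc radius, um.
#' @param n_eval transits per bisection evaluation.
#' @param dt step size, minutes.
#' @param tol relative tolerance on the achieved mean (default 3\%).
#' @return A \code{\link{spleenSection}} with the calibrated aperture;
#'   attribute \code{calibration} records the achieved mean, \code{n_eval},
#'   \code{dt} and the bracket.
#' @export
calibrateSpleen <- function(target_mean = 6, motility = 60, radius = 120,
                            n_eval = 6000, dt = 0.2, tol = 0.03) {
  if (target_mean <= 0) stop("'target_mean' must be positive")
  mean_at <- function(alpha)
    mean(cpp_disc_transit(n_eval, radius, alpha, motility, dt))
  lo <- 0.05; hi <- pi - 0.05
  m_lo <- mean_at(lo); m_hi <- mean_at(hi)
  if (target_mean > m_lo || target_mean < m_hi)
    stop(sprintf(
      "target mean %.3g h not bracketed: aperture in (%.2g, %.2g) rad gives means (%.3g, %.3g) h; adjust the radius",
      target_mean, lo, hi, m_lo, m_hi))
  for (it in 1:12) {
    mid <- (lo + hi) / 2
    m <- mean_at(mid)
    if (abs(m - target_mean) / target_mean < tol / 2) break
    if (m > target_mean) lo <- mid else hi <- mid
  }
  geom <- spleenSection(radius = radius, aperture = mid, motility = motility)
  attr(geom, "calibration") <- list(target_mean_h = target_mean,
                                    achieved_mean_h = m,
                                    n_eval = n_eval, dt_min = dt,
                                    bracket = c(lo, hi))
  geom
}
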