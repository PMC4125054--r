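# Capture-time analysis: how long after antigen appearance does a
# circulating cognate T cell get retained in a draining LN? Combines the
# circulation model (between organs) with the priming law (within dLNs).
#
# For deterministic LN transit the expectation has a closed form: a cell
# reaches its first LN at mean time t0, makes a geometric number N of
# unsuccessful LN visits (success probability f*P per visit, where f is the
# dLN fraction and P the per-dLN-visit retention probability), pays
# T_det + tau_b per failed cycle (tau_b = mean blood+spleen time between
# consecutive LN visits), and finally spends the truncated retention time
# theta = E[A | A < T_det] inside the last dLN:
#
#   E[T_cap] = t0 + E[N] (T_det + tau_b) + theta,  E[N] = (1 - fP) / (fP)

#' Retention probability per dLN visit
#'
#' Probability that the retention time A falls within one LN dwell. For
#' deterministic transit this is the retention CDF at the fixed dwell. For
#' stochastic (first-passage) transit with probabilistic priming
#' (\code{required_contacts = 1}) the closed form
#' \eqn{1 - z\,\mathrm{csch}(z)} with \eqn{z = R\sqrt{\mu/M}} applies; for
#' shapes > 1 the probability is computed as
#' \eqn{\int_0^\infty f_A(a)\,P(T > a)\,da} by numerical integration of the
#' Gamma density against the transit survival series.
#'
#' @param params a \code{\link{primingParams}}.
#' @param mode a \code{\link{transitMode}}.
#' @param geom an \code{\link{lnSphere}} (stochastic mode).
#' @return probability in [0, 1].
#' @export
probRetainedPerVisit <- function(params, mode = transitMode(),
                                 geom = lnSphere()) {
  stopifnot(inherits(params, "priming_params"), inherits(mode, "transit_mode"))
  if (mode$kind == "deterministic")
    return(retentionCDF(mode$T_det, params))
  mu <- successRate(params)
  if (params$required_contacts == 1) {
    # 1 - E[exp(-mu T)] = 1 - z csch(z)
    return(1 - lnTransitLaplace(mu, geom))
  }
  f <- function(a) stats::dgamma(a, shape = params$required_contacts, rate = mu) *
    lnSurvival(a, geom)
  upper <- stats::qgamma(1 - 1e-10, shape = params$required_contacts, rate = mu)
  stats::integrate(Vectorize(f), 0, upper, rel.tol = 1e-8)$value
}

#' Mean blood + spleen time between consecutive LN visits
#'
#' Between two LN visits a cell makes a geometric number of blood sojourns
#' (each ending in a LN with probability \eqn{p = \Sigma\sigma_i/\Lambda}),
#' interleaved with spleen transits:
#' \eqn{\tau_b = (1/p)\,(1/\Lambda) + ((1-p)/p)\,\bar T_{spleen}}.
#' The spleen mean is taken from the body's transit-time table.
#'
#' @param body a \code{\link{bodyConfig}} (baseline rates; no ramp).
#' @return hours.
#' @export
meanInterVisitTime <- function(body = bodyConfig()) {
  stopifnot(inherits(body, "body_config"))
  lam <- body$spleen_entry_rate + sum(body$ln_entry_rates)
  p_ln <- sum(body$ln_entry_rates) / lam
  sp_mean <- mean(.spleenQuantileTable(body$spleen_geom)$t)
  (1 / p_ln) * (1 / lam) + ((1 - p_ln) / p_ln) * sp_mean
}

# memoized short Monte Carlo for t0, the mean time at which a
# steady-state-initialized cell first enters a LN after t = 0. Convention
# "next_entry": every cell counts its first LN *entry* at or after t = 0,
# so cells inside a LN at t = 0 first finish their residual dwell.
# Convention "in_ln_counts": cells inside any LN at t = 0 get t0 = 0.
# Runs on an isolated RNG stream so results are deterministic and the
# caller's stream is untouched.
.t0_cache <- new.env(parent = emptyenv())

#' Mean time to the first LN entry from steady state
#'
#' @param body a \code{\link{bodyConfig}}.
#' @param mode a \code{\link{transitMode}} (the steady state depends on it).
#' @param convention \code{"next_entry"} (default) or \code{"in_ln_counts"};
#'   see Details in the methods vignette.
#' @param n_cells Monte Carlo size (cached per configuration).
#' @return hours.
#' @export
meanFirstLnEntry <- function(body = bodyConfig(), mode = transitMode(),
                             convention = c("next_entry", "in_ln_counts"),
                             n_cells = 4000) {
  convention <- match.arg(convention)
  key <- paste(signif(body$spleen_entry_rate, 8), signif(sum(body$ln_entry_rates), 8),
               signif(body$ln_geom$radius, 8), signif(body$ln_geom$motility, 8),
               signif(body$spleen_geom$radius, 8), signif(body$spleen_geom$aperture, 8),
               mode$kind, signif(mode$T_det, 8), convention, n_cells, sep = "|")
  if (!is.null(.t0_cache[[key]])) return(.t0_cache[[key]])
  seed_old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(seed_old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", seed_old, envir = globalenv())
  })
  set.seed(20140808L)
  sim <- simulateCohort(n_cells, body, horizon = 400, mode = mode,
                        burn_in = TRUE, record = TRUE)
  ep <- sim$episodes
  is_ln <- ep$compartment >= 2L
  entries <- ep[is_ln & ep$t_entry_h >= 0, ]
  first <- tapply(entries$t_entry_h, entries$cell_id, min)
  t0_cell <- rep(NA_real_, n_cells)
  t0_cell[as.integer(names(first))] <- as.numeric(first)
  if (convention == "in_ln_counts") {
    inside0 <- unique(ep$cell_id[is_ln & ep$t_entry_h < 0 & ep$t_exit_h > 0])
    t0_cell[inside0] <- 0
  }
  val <- mean(t0_cell, na.rm = TRUE)
  .t0_cache[[key]] <- val
  val
}

#' Closed-form expected capture time for deterministic LN transit
#'
#' Valid for a constant LN dwell, constant dLN entry rates and constant
#' priming parameters. The truncated-Gamma mean uses the identity
#' \eqn{E[A\,1(A<T)] = (n/\mu) F_{n+1,\mu}(T)}.
#'
#' @param f fraction of dLN spheres among all LN spheres, in (0, 1].
#' @param priming a \code{\link{primingParams}}.
#' @param T_det fixed LN dwell, hours.
#' @param body a \code{\link{bodyConfig}} (supplies tau_b and t0).
#' @param t0 mean time to the first LN entry; default computed by
#'   \code{\link{meanFirstLnEntry}} at the deterministic steady state. Pass
#'   0 to study the t0-free part.
#' @param convention t0 convention, see \code{\link{meanFirstLnEntry}}.
#' @return An object of class \code{capture_solution}: list with
#'   \code{expected_capture_h} and components \code{t0}, \code{tau_b},
#'   \code{E_N}, \code{P}, \code{theta}.
#' @export
expectedCaptureTime <- function(f, priming, T_det, body = bodyConfig(),
                                t0 = NULL,
                                convention = c("next_entry", "in_ln_counts")) {
  if (!is.numeric(f) || length(f) != 1L || f <= 0 || f > 1)
    stop("'f' must be in (0, 1]")
  stopifnot(inherits(priming, "priming_params"))
  if (T_det <= 0) stop("'T_det' must be positive")
  convention <- match.arg(convention)
  n <- priming$required_contacts
  mu <- successRate(priming)
  P <- retentionCDF(T_det, priming)
  if (f * P <= 0)
    stop("f * P = 0: the expected capture time is infinite")
  tau_b <- meanInterVisitTime(body)
  if (is.null(t0))
    t0 <- meanFirstLnEntry(body, transitMode("deterministic", T_det = T_det),
                           convention = convention)
  theta <- (n / mu) * stats::pgamma(T_det, shape = n + 1, rate = mu) / P
  E_N <- (1 - f * P) / (f * P)
  structure(
    list(expected_capture_h = t0 + E_N * (T_det + tau_b) + theta,
         t0 = t0, tau_b = tau_b, E_N = E_N, P = P, theta = theta,
         f = f, T_det = T_det, priming = priming),
    class = "capture_solution")
}

#' @export
print.capture_solution <- function(x, ...) {
  cat(sprintf("Expected capture time %.4g h (%.3g d)\n",
              x$expected_capture_h, x$expected_capture_h / 24))
  cat(sprintf("  components: t0 = %.3g h, tau_b = %.3g h, E[N] = %.4g, P = %.4g, theta = %.3g h\n",
              x$t0, x$tau_b, x$E_N, x$P, x$theta))
  invisible(x)
}

#' Monte Carlo capture times
#'
#' Simulates steady-state-initialized cells until retention in a draining
#' LN. The dLN fraction \code{f} is applied per LN visit (each visit is a
#' dLN visit with probability f, the exact meaning of a dLN fraction under
#' even entry rates). Works with both transit modes and any priming law.
#'
#' @param n_cells cohort size.
#' @param f dLN fraction in (0, 1].
#' @param priming a \code{\link{primingParams}}.
#' @param mode a \code{\link{transitMode}}.
#' @param body a \code{\link{bodyConfig}} (must have no ramp).
#' @param horizon censoring horizon in hours; cells not captured by then
#'   return NA.
#' @param burn_in steady-state initialization (default TRUE).
#' @param initial_dln \code{"exclude"} (default) drops cells that are
#'   already inside a draining sphere when the antigen appears, matching
#'   the closed-form derivation which follows a cell that is not in a dLN
#'   at that time; \code{"include"} keeps them (they can be retained
#'   during the remainder of their current dwell).
#' @return numeric vector of per-cell capture times in hours (NA censored),
#'   with the fraction censored as attribute \code{censored}.
#' @export
captureTimeMC <- function(n_cells, f, priming, mode = transitMode(),
                          body = bodyConfig(), horizon = NULL,
                          burn_in = TRUE,
                          initial_dln = c("exclude", "include")) {
  initial_dln <- match.arg(initial_dln)
  if (!is.numeric(f) || length(f) != 1L || f <= 0 || f > 1)
    stop("'f' must be in (0, 1]")
  if (is.null(horizon)) {
    # generous default: ~40x the rough per-visit scale
    P_guess <- max(probRetainedPerVisit(priming, mode, body$ln_geom), 1e-4)
    horizon <- max(2000, 40 * (1 / (f * P_guess)) *
                     (meanInterVisitTime(body) +
                        if (mode$kind == "deterministic") mode$T_det else lnMeanTransit(body$ln_geom)))
  }
  sim <- .runCohort(n_cells, body, horizon, mode, priming, burn_in,
                    dln_visit_prob = f, record = FALSE)
  out <- sim$retention_time
  if (initial_dln == "exclude") out <- out[!sim$initial_dln]
  attr(out, "censored") <- mean(is.na(out))
  out
}

#' Optimal deterministic LN transit time
#'
#' Minimizes the analytic expected capture time over the fixed dwell
#' \eqn{T} on (0, 96] h. The first-arrival term t0 is an additive constant
#' at fixed steady state and is excluded from the objective (see the
#' methods vignette for the sensitivity of the optimum to a T-dependent
#' t0). A grid pre-scan guards against local minima; if the objective is
#' flat near the optimum a warning reports the flat interval.
#'
#' @param f dLN fraction in (0, 1].
#' @param priming a \code{\link{primingParams}}.
#' @param body a \code{\link{bodyConfig}}.
#' @param interval search interval in hours.
#' @return optimal transit time in hours, with the minimal objective as
#'   attribute \code{objective_h}.
#' @export
optimalTransitTime <- function(f, priming, body = bodyConfig(),
                               interval = c(0.05, 96)) {
  if (!is.numeric(f) || length(f) != 1L || f <= 0 || f > 1)
    stop("'f' must be in (0, 1]")
  stopifnot(inherits(priming, "priming_params"))
  n <- priming$required_contacts
  mu <- successRate(priming)
  tau_b <- meanInterVisitTime(body)
  obj <- function(T_det) {
    P <- stats::pgamma(T_det, shape = n, rate = mu)
    theta <- (n / mu) * stats::pgamma(T_det, shape = n + 1, rate = mu) / pmax(P, 1e-300)
    (1 - f * P) / (f * pmax(P, 1e-300)) * (T_det + tau_b) + theta
  }
  grid <- exp(seq(log(interval[1]), log(interval[2]), length.out = 400))
  vals <- obj(grid)
  i <- which.min(vals)
  lo <- grid[max(1, i - 2)]; hi <- grid[min(length(grid), i + 2)]
  opt <- stats::optimize(obj, c(lo, hi), tol = 1e-6)
  flat <- grid[vals <= opt$objective * 1.001]
  if (length(flat) > 20)
    warning(sprintf("objective is flat near the optimum (within 0.1%% over [%.3g, %.3g] h)",
                    min(flat), max(flat)))
  structure(opt$minimum, objective_h = opt$objective)
}

#' Benefit/risk table of LN transit optimization
#'
#' For each antigen dose in \code{optimized_for} (given as required contact
#' numbers), computes the optimal deterministic transit time, then compares
#' the capture time of cells using that fixed dwell against cells with
#' stochastic (first-passage) transit, across the doses in
#' \code{evaluated_at}. Entries are fold differences
#' deterministic / stochastic: values below 1 on the diagonal are the
#' benefit of perfectly timed transit, values far above 1 off the diagonal
#' are the risk of optimizing for the wrong dose. Deterministic capture
#' times are analytic; stochastic ones are Monte Carlo. Both sides use the
#' same t0 convention.
#'
#' @param optimized_for integer vector of required-contact doses to
#'   optimize the transit for.
#' @param evaluated_at integer vector of doses to evaluate against
#'   (default: same as \code{optimized_for}).
#' @param f dLN fraction.
#' @param contact_rate shared effective contact rate, per hour.
#' @param body a \code{\link{bodyConfig}}.
#' @param n_cells Monte Carlo cells per stochastic capture estimate.
#' @return matrix of fold differences, rows = optimized-for dose, columns =
#'   evaluated dose, with the optimal transit times as attribute
#'   \code{optimal_transit_h} and the stochastic means as attribute
#'   \code{stochastic_capture_h}.
#' @export
benefitRiskMatrix <- function(optimized_for = c(2, 4, 6, 8, 10),
                              evaluated_at = optimized_for,
                              f = 0.25, contact_rate = 1,
                              body = bodyConfig(), n_cells = 2000) {
  T_opt <- vapply(optimized_for, function(nn)
    as.numeric(optimalTransitTime(f, primingParams(contact_rate, 1, nn), body)),
    numeric(1))
  stoch <- vapply(evaluated_at, function(nn) {
    ct <- captureTimeMC(n_cells, f, primingParams(contact_rate, 1, nn),
                        transitMode("stochastic"), body)
    mean(ct, na.rm = TRUE)
  }, numeric(1))
  out <- matrix(NA_real_, length(optimized_for), length(evaluated_at),
                dimnames = list(optimized_for = optimized_for,
                                evaluated_at = evaluated_at))
  for (i in seq_along(optimized_for)) {
    t0_det <- meanFirstLnEntry(body, transitMode("deterministic", T_det = T_opt[i]))
    for (j in seq_along(evaluated_at)) {
      det <- expectedCaptureTime(f, primingParams(contact_rate, 1, evaluated_at[j]),
                                 T_opt[i], body, t0 = t0_det)
      out[i, j] <- det$expected_capture_h / stoch[j]
    }
  }
  attr(out, "optimal_transit_h") <- stats::setNames(T_opt, optimized_for)
  attr(out, "stochastic_capture_h") <- stats::setNames(stoch, evaluated_at)
  out
}
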