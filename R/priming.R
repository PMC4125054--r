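#' Priming parameters for T cell retention in a draining lymph node
#'
#' The general priming model combines two classic hypotheses about how serial
#' brief T cell--DC contacts lead to arrest (retention): \emph{signal
#' integration}, where a cell is retained after accumulating
#' \code{required_contacts} successful cognate contacts, and
#' \emph{probabilistic priming}, where every new contact independently
#' triggers retention with probability \code{success_prob}. Cognate DC
#' encounters arrive as a Poisson process with rate \code{contact_rate}
#' (per hour), so successful contacts arrive at the effective rate
#' \eqn{\mu = \lambda p}, and the retention time is Gamma distributed with
#' shape \code{required_contacts} and rate \eqn{\mu}.
#'
#' Only \eqn{\mu = \lambda p} is identifiable from retention timecourses;
#' \code{contact_rate} and \code{success_prob} enter the retention law through
#' their product alone.
#'
#' @param contact_rate cognate DC encounter rate, events per hour.
#' @param success_prob per-contact probability that a cognate signal is
#'   transmitted, in (0, 1].
#' @param required_contacts number of successful contacts needed for
#'   retention; an integer in event-level simulation, any real >= 1 in
#'   fitting.
#' @return An object of class \code{priming_params}.
#' @examples
#' # signal integration, 8 contacts at 1/h: mean retention 8 h
#' p <- primingParams(contact_rate = 1, required_contacts = 8)
#' retentionMean(p)
#' # probabilistic priming at the same mean
#' q <- primingParams(contact_rate = 1, success_prob = 1/8,
#'                    required_contacts = 1)
#' retentionMean(q)
#' @export
primingParams <- function(contact_rate = 1, success_prob = 1,
                          required_contacts = 1) {
  if (!is.numeric(contact_rate) || length(contact_rate) != 1L ||
      !is.finite(contact_rate) || contact_rate <= 0)
    stop("'contact_rate' must be a single positive number (per hour)")
  if (!is.numeric(success_prob) || length(success_prob) != 1L ||
      success_prob <= 0 || success_prob > 1)
    stop("'success_prob' must be in (0, 1]")
  if (!is.numeric(required_contacts) || length(required_contacts) != 1L ||
      !is.finite(required_contacts) || required_contacts < 1)
    stop("'required_contacts' must be >= 1")
  structure(
    list(contact_rate = contact_rate,
         success_prob = success_prob,
         required_contacts = required_contacts),
    class = "priming_params")
}

#' @export
print.priming_params <- function(x, ...) {
  cat(sprintf(
    "Priming parameters: lambda = %g /h, p = %g, n = %g (mu = %g /h)\n",
    x$contact_rate, x$success_prob, x$required_contacts, successRate(x)))
  cat(sprintf("  mean retention time %.4g h, variance %.4g h^2\n",
              retentionMean(x), retentionVariance(x)))
  invisible(x)
}

#' Effective successful-contact rate
#'
#' @param params a \code{\link{primingParams}} object.
#' @return \eqn{\mu = \lambda p} in events per hour, the only rate
#'   identifiable from retention data.
#' @export
successRate <- function(params) {
  stopifnot(inherits(params, "priming_params"))
  params$contact_rate * params$success_prob
}

#' Retention-time distribution functions
#'
#' The time from lymph-node entry to retention is Gamma distributed with
#' shape \code{required_contacts} and rate \eqn{\mu = \lambda p}:
#' \code{retentionCDF} is the regularized lower incomplete gamma function,
#' and the mean and variance are \eqn{n/\mu} and \eqn{n/\mu^2}. With
#' \code{required_contacts = 1} the law is exponential (pure probabilistic
#' priming).
#'
#' @param t time since LN entry, hours (vectorized, must be >= 0).
#' @param params a \code{\link{primingParams}} object.
#' @return \code{retentionCDF}: P(retention time <= t).
#' @export
retentionCDF <- function(t, params) {
  stopifnot(inherits(params, "priming_params"))
  if (any(!is.finite(t) | t < 0)) stop("'t' must be finite and >= 0")
  stats::pgamma(t, shape = params$required_contacts, rate = successRate(params))
}

#' @rdname retentionCDF
#' @return \code{retentionMean}: mean retention time in hours.
#' @export
retentionMean <- function(params) {
  stopifnot(inherits(params, "priming_params"))
  params$required_contacts / successRate(params)
}

#' @rdname retentionCDF
#' @return \code{retentionVariance}: variance of the retention time, hours^2.
#' @export
retentionVariance <- function(params) {
  stopifnot(inherits(params, "priming_params"))
  params$required_contacts / successRate(params)^2
}

#' Sample retention times
#'
#' Draws retention times as sums of \code{required_contacts} independent
#' exponential waiting times with rate \eqn{\mu} (for integer shape), or from
#' the Gamma law directly for non-integer shape. Uses R's global RNG; call
#' \code{set.seed} for reproducibility.
#'
#' @param n number of samples.
#' @param params a \code{\link{primingParams}} object.
#' @return numeric vector of retention times in hours.
#' @export
sampleRetentionTime <- function(n, params) {
  stopifnot(inherits(params, "priming_params"))
  shape <- params$required_contacts
  mu <- successRate(params)
  if (shape == round(shape) && shape <= 64) {
    # explicit sum of exponential inter-contact waits
    colSums(matrix(stats::rexp(n * shape, rate = mu), nrow = shape))
  } else {
    stats::rgamma(n, shape = shape, rate = mu)
  }
}

#' Simulate an event-level DC contact history
#'
#' Generates the timestamped cognate DC encounters of one cell: contacts
#' arrive at rate \code{contact_rate}; each succeeds (transmits a cognate
#' signal) with probability \code{success_prob}; the cell is retained at the
#' \code{required_contacts}-th success. This event-level process is the
#' ground truth behind \code{\link{retentionCDF}} and is used to cross-check
#' the Gamma law.
#'
#' @param params a \code{\link{primingParams}} object
#'   (\code{required_contacts} must be an integer here).
#' @param horizon simulation horizon in hours.
#' @return A list with \code{events} (data.frame: \code{time_h},
#'   \code{success}) and \code{retention_time_h} (NA if the cell is not
#'   retained before the horizon).
#' @export
simulateContactHistory <- function(params, horizon) {
  stopifnot(inherits(params, "priming_params"))
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0)
    stop("'horizon' must be a single positive number of hours")
  if (params$required_contacts != round(params$required_contacts))
    stop("event-level simulation needs integer 'required_contacts'")
  times <- numeric(0)
  t <- 0
  repeat {
    t <- t + stats::rexp(1, rate = params$contact_rate)
    if (t > horizon) break
    times <- c(times, t)
  }
  success <- stats::runif(length(times)) <= params$success_prob
  k <- which(cumsum(success) >= params$required_contacts)
  ret <- if (length(k)) times[k[1]] else NA_real_
  list(events = data.frame(time_h = times, success = success),
       retention_time_h = ret)
}

#' Unique-contact conversion factor
#'
#' In a persistent random walk through a large 3D T cell zone roughly 2/3 of
#' all DC contacts are with a DC not met before. Probabilistic priming only
#' counts \emph{new} DCs, so when the two priming families are compared at
#' the same \emph{true} underlying contact rate, the effective contact rate
#' of probabilistic priming is 2/3 that of signal integration. By default
#' all functions in this package compare at equal \emph{effective} rates;
#' apply this factor explicitly (once) when a scenario requests a same-true-
#' rate comparison.
#'
#' @return The dimensionless factor 2/3.
#' @export
uniqueContactFactor <- function() 2 / 3

#' @rdname uniqueContactFactor
#' @param params a \code{\link{primingParams}} object whose
#'   \code{contact_rate} is a true (not effective) contact rate.
#' @return \code{applyUniqueContactFactor}: the parameters with
#'   \code{contact_rate} scaled by 2/3 and tagged so that applying the factor
#'   twice is an error.
#' @export
applyUniqueContactFactor <- function(params) {
  stopifnot(inherits(params, "priming_params"))
  if (isTRUE(attr(params, "unique_contact_adjusted")))
    stop("unique-contact factor already applied to these parameters")
  out <- primingParams(params$contact_rate * uniqueContactFactor(),
                       params$success_prob, params$required_contacts)
  attr(out, "unique_contact_adjusted") <- TRUE
  out
}
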