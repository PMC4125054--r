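# Logit-scale fitting of the Gamma retention law to windowed retention
# timecourses, with cross-experiment parameter sharing and BIC model
# selection between the general model and its two pure restrictions.
#
# Families (E = number of experiments):
#   general:             per-experiment shape n_e and rate mu_e    (k = 2E)
#   signal_integration:  global rate mu, per-experiment shape n_e  (k = E+1)
#                        (success probability fixed at 1)
#   probabilistic:       per-experiment rate mu_e, shape fixed 1   (k = E)
# Fitting minimizes the duration-weighted squared error between
# logit(observed fraction) and logit(model CDF); fractions are clipped to
# [0.01, 0.99] before the transform (corrected fractions of exactly 0 occur
# at early times). The BIC uses the Gaussian-residuals-on-logit-scale
# convention BIC = N ln(RSS/N) + k ln N.

.FAMILIES <- c("general", "signal_integration", "probabilistic")

.clipLogit <- function(p, clip = c(0.01, 0.99))
  stats::qlogis(pmin(clip[2], pmax(clip[1], p)))

# weighted logit-scale RSS of one experiment under (shape, rate)
.rssOne <- function(time_h, y, w, shape, rate, clip) {
  pred <- stats::pgamma(time_h, shape = shape, rate = rate)
  sum(w * (y - .clipLogit(pred, clip))^2)
}

# best (shape, rate) for one experiment; multi-start 2-d quasi-Newton
.fitGeneralOne <- function(time_h, y, w, clip) {
  obj <- function(par) .rssOne(time_h, y, w, exp(par[1]), exp(par[2]), clip)
  starts <- expand.grid(n0 = c(1, 2, 4, 8, 16), mu0 = c(0.3, 1, 3))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- try(stats::optim(c(log(starts$n0[i]), log(starts$mu0[i])), obj,
                            method = "L-BFGS-B",
                            lower = c(0, -6), upper = c(log(128), 6)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("general-model fit failed to converge on any start")
  list(shape = exp(best$par[1]), rate = exp(best$par[2]), rss = best$value)
}

# robust 1-d minimization on [lo, hi]: coarse grid scan, then local refine
# around the best knot (the objective can have plateaus from clipping)
.gridOptimize <- function(fn, lo, hi, n_grid = 25) {
  grid <- seq(lo, hi, length.out = n_grid)
  vals <- vapply(grid, fn, numeric(1))
  i <- which.min(vals)
  opt <- stats::optimize(fn, c(grid[max(1, i - 1)], grid[min(n_grid, i + 1)]))
  if (opt$objective <= vals[i]) opt
  else list(minimum = grid[i], objective = vals[i])
}

# best shape for one experiment at a fixed global rate
.fitShapeOne <- function(time_h, y, w, rate, clip) {
  opt <- .gridOptimize(function(a) .rssOne(time_h, y, w, exp(a), rate, clip),
                       0, log(128))
  list(shape = exp(opt$minimum), rss = opt$objective)
}

#' Fit a priming model to retention timecourses
#'
#' @param data data.frame with columns \code{experiment_id}, \code{time_h}
#'   (hours post LN entry), \code{fraction} (corrected retained fraction)
#'   and \code{weight} (total track duration of the point; used as the
#'   residual weight, normalized to mean 1). Typically the output of
#'   \code{\link{windowRetentionSeries}}.
#' @param family \code{"general"}, \code{"signal_integration"} or
#'   \code{"probabilistic"}; see the package overview for the sharing
#'   structure of each.
#' @param clip fractions are clipped to this range before the logit.
#' @return An object of class \code{retention_fit}: list with
#'   \code{estimates} (per-experiment shape and rate), \code{k}, \code{N},
#'   \code{rss} (weighted, logit scale), \code{bic} and \code{family}.
#' @export
fitRetentionModel <- function(data, family = .FAMILIES, clip = c(0.01, 0.99)) {
  family <- match.arg(family, .FAMILIES)
  need <- c("experiment_id", "time_h", "fraction", "weight")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("data lacks column(s): ", paste(miss, collapse = ", "))
  exps <- unique(data$experiment_id)
  if (any(table(data$experiment_id) < 2))
    stop("each experiment needs at least 2 retention points")
  w <- data$weight / mean(data$weight)
  y <- .clipLogit(data$fraction, clip)
  by_exp <- lapply(exps, function(e) {
    sel <- data$experiment_id == e
    list(t = data$time_h[sel], y = y[sel], w = w[sel])
  })
  names(by_exp) <- exps

  if (family == "general") {
    fits <- lapply(by_exp, function(d) .fitGeneralOne(d$t, d$y, d$w, clip))
    est <- data.frame(experiment_id = exps,
                      shape = vapply(fits, `[[`, numeric(1), "shape"),
                      rate = vapply(fits, `[[`, numeric(1), "rate"))
    rss <- sum(vapply(fits, `[[`, numeric(1), "rss"))
    k <- 2L * length(exps)
  } else if (family == "probabilistic") {
    fits <- lapply(by_exp, function(d) {
      opt <- .gridOptimize(function(b) .rssOne(d$t, d$y, d$w, 1, exp(b), clip),
                           -6, 6)
      list(shape = 1, rate = exp(opt$minimum), rss = opt$objective)
    })
    est <- data.frame(experiment_id = exps,
                      shape = 1,
                      rate = vapply(fits, `[[`, numeric(1), "rate"))
    rss <- sum(vapply(fits, `[[`, numeric(1), "rss"))
    k <- length(exps)
  } else { # signal integration: shared rate, per-experiment shape
    prof <- function(b) {
      sum(vapply(by_exp, function(d)
        .fitShapeOne(d$t, d$y, d$w, exp(b), clip)$rss, numeric(1)))
    }
    bgrid <- seq(-4, 4, length.out = 33)
    vals <- vapply(bgrid, prof, numeric(1))
    i <- which.min(vals)
    opt <- stats::optimize(prof, c(bgrid[max(1, i - 1)], bgrid[min(33, i + 1)]))
    mu <- exp(opt$minimum)
    fits <- lapply(by_exp, function(d) .fitShapeOne(d$t, d$y, d$w, mu, clip))
    est <- data.frame(experiment_id = exps,
                      shape = vapply(fits, `[[`, numeric(1), "shape"),
                      rate = mu)
    rss <- opt$objective
    k <- length(exps) + 1L
  }

  N <- nrow(data)
  if (N <= k) warning("fewer points than parameters; BIC is unreliable")
  structure(
    list(family = family, estimates = est, k = k, N = N, rss = rss,
         bic = N * log(rss / N) + k * log(N), clip = clip),
    class = "retention_fit")
}

#' @export
print.retention_fit <- function(x, ...) {
  cat(sprintf("Retention fit: %s model, k = %d parameters, N = %d points\n",
              x$family, x$k, x$N))
  cat(sprintf("  weighted logit RSS = %.4g, BIC = %.2f\n", x$rss, x$bic))
  print(x$estimates, row.names = FALSE)
  invisible(x)
}

#' Fitted retention curve of one experiment
#'
#' @param fit a \code{retention_fit}.
#' @param experiment_id which experiment.
#' @param time_h evaluation times, hours post LN entry.
#' @return predicted retained fractions.
#' @export
fittedRetention <- function(fit, experiment_id, time_h) {
  stopifnot(inherits(fit, "retention_fit"))
  i <- match(experiment_id, fit$estimates$experiment_id)
  if (is.na(i)) stop("unknown experiment_id")
  stats::pgamma(time_h, shape = fit$estimates$shape[i],
                rate = fit$estimates$rate[i])
}

#' Evidence label on the Kass-Raftery scale
#'
#' @param delta_bic BIC increase relative to the best model.
#' @return character label.
#' @export
bicEvidence <- function(delta_bic) {
  cut(delta_bic, c(-Inf, 2, 6, 10, Inf),
      labels = c("weak", "positive", "strong", "very strong"),
      right = TRUE) |> as.character()
}

#' Model-selection report
#'
#' Fits the general model and the requested restrictions to the same data
#' and tabulates parameter counts, residuals, BIC and the BIC increase of
#' each restriction over the general model.
#'
#' @param data retention points, see \code{\link{fitRetentionModel}}.
#' @param restrictions subset of \code{c("signal_integration",
#'   "probabilistic")} (may be empty, in which case only the general model
#'   is reported).
#' @return data.frame with one row per fitted family (columns
#'   \code{family}, \code{k}, \code{rss}, \code{bic}, \code{delta_bic},
#'   \code{evidence_against}), with the fits as attribute \code{fits}.
#' @export
modelSelectionReport <- function(data,
                                 restrictions = c("signal_integration",
                                                  "probabilistic")) {
  if (length(restrictions))
    restrictions <- match.arg(restrictions,
                              c("signal_integration", "probabilistic"),
                              several.ok = TRUE)
  fams <- c("general", restrictions)
  fits <- lapply(fams, function(f) fitRetentionModel(data, f))
  names(fits) <- fams
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  out <- data.frame(
    family = fams,
    k = vapply(fits, `[[`, integer(1), "k"),
    rss = vapply(fits, `[[`, numeric(1), "rss"),
    bic = bics,
    delta_bic = bics - bics["general"],
    row.names = NULL)
  out$evidence_against <- ifelse(out$family == "general", "",
                                 bicEvidence(out$delta_bic))
  attr(out, "fits") <- fits
  out
}
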