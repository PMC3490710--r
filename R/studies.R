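#' Confidence band for a predicted quantity over time
#'
#' Computes a prediction (or validation) confidence interval at each of a
#' series of time points by profiling the prediction, and assembles them
#' into a time band.  Between the profiled times the bounds are
#' interconnected by cubic piecewise interpolation (a monotonicity
#' preserving Hermite variant, so the band cannot overshoot between knots);
#' unbounded time points break the interpolated segment.
#'
#' @param model An [ode_model()].
#' @param data Dataset `data.frame` the fit is based on.
#' @param fit A [fit_model()] result.
#' @param state_or_expr State name or expression string to predict.
#' @param times Time points (>= 2) at which intervals are profiled.
#' @param alpha Confidence level.
#' @param scan A [scan_config()].
#' @param mode `"prediction"` (PCI band) or `"validation"` (VCI band).
#' @param sd Validation measurement error (required for
#'   `mode = "validation"`).
#' @param input Input condition of the prediction.
#' @return An object of class `confidence_band`: a `data.frame` with
#'   columns `time`, `estimate`, `lower`, `upper`, `unbounded_lower`,
#'   `unbounded_upper`, `quality`, with the level, mode, expression and
#'   interpolation method as attributes.
#' @export
pci_band <- function(model, data, fit, state_or_expr, times, alpha = 0.9,
                     scan = scan_config(),
                     mode = c("prediction", "validation"), sd = NULL,
                     input = "default") {
  mode <- match.arg(mode)
  times <- as.numeric(times)
  if (length(times) < 2L) stop_config("a band needs at least 2 time points")
  if (mode == "validation" && (!is_scalar_number(sd) || sd <= 0))
    stop_config("validation mode needs a positive 'sd'")
  threshold <- profile_threshold(alpha)
  rows <- lapply(times, function(tp) {
    tgt <- prediction_target(state_or_expr, tp, input)
    curve <- if (mode == "prediction")
      ppl_scan(model, data, tgt, fit, scan = scan, alpha = alpha)
    else
      vpl_scan(model, data, validation_setup(tgt, sd), fit, scan = scan,
               alpha = alpha)
    ci <- interval_from_curve(curve, threshold, alpha)
    data.frame(time = tp, estimate = ci$estimate,
               lower = ci$lower, upper = ci$upper,
               unbounded_lower = ci$unbounded_lower,
               unbounded_upper = ci$unbounded_upper,
               quality = if (isTRUE(attr(curve, "unreliable")))
                 "unreliable" else "ok")
  })
  band <- do.call(rbind, rows)
  attr(band, "state") <- state_or_expr
  attr(band, "alpha") <- alpha
  attr(band, "mode") <- mode
  attr(band, "sd") <- sd
  attr(band, "interpolation") <- "monoH.FC"
  class(band) <- c("confidence_band", "data.frame")
  band
}

#' Interpolate a confidence band between its knots
#'
#' Evaluates the cubic piecewise (monotone Hermite) interpolation of the
#' band bounds at new times.  Maximal runs of consecutive bounded knots are
#' interpolated independently; times falling into a segment broken by an
#' unbounded knot give `NA`.  At the knots themselves the raw interval
#' bounds are returned exactly.
#'
#' @param band A [pci_band()] result.
#' @param times Times at which to evaluate the band.
#' @return `data.frame` with columns `time`, `lower`, `upper`.
#' @export
interpolate_band <- function(band, times) {
  stopifnot(inherits(band, "confidence_band"))
  times <- as.numeric(times)
  interp_side <- function(bvals, unb) {
    out <- rep(NA_real_, length(times))
    good <- which(!unb & is.finite(bvals))
    if (!length(good)) return(out)
    runs <- split(good, cumsum(c(1, diff(good) != 1)))
    for (run in runs) {
      if (length(run) == 1L) {
        out[times == band$time[run]] <- bvals[run]
        next
      }
      f <- if (length(run) >= 3L)
        stats::splinefun(band$time[run], bvals[run], method = "monoH.FC")
      else stats::approxfun(band$time[run], bvals[run])
      sel <- times >= min(band$time[run]) & times <= max(band$time[run])
      out[sel] <- f(times[sel])
    }
    out
  }
  data.frame(time = times,
             lower = interp_side(band$lower, band$unbounded_lower),
             upper = interp_side(band$upper, band$unbounded_upper))
}

#' @export
print.confidence_band <- function(x, ...) {
  cat("<confidence_band> ", attr(x, "mode"), " band for ", attr(x, "state"),
      " at alpha = ", attr(x, "alpha"), "\n", sep = "")
  print(as.data.frame(x))
  invisible(x)
}

#' Classify practical observability from a confidence band
#'
#' A predicted quantity is practically observable given the data when its
#' prediction confidence interval is bounded at every evaluated time; any
#' unbounded time point (a profile that stayed flat below the threshold up
#' to the scan limit) makes it non-observable.  Time points with
#' degenerate, width-zero intervals (e.g. an initial condition fixed by the
#' model) are bounded and therefore never offend.
#'
#' @param band A [pci_band()] result.
#' @return An object of class `observability`: list with `status`
#'   (`"observable"` / `"non_observable"`) and `detail`, a `data.frame` of
#'   offending times and sides.
#' @export
classify_observability <- function(band) {
  stopifnot(inherits(band, "confidence_band"))
  off <- band$unbounded_lower | band$unbounded_upper
  detail <- data.frame(
    time = band$time[off],
    side = ifelse(band$unbounded_lower[off] & band$unbounded_upper[off],
                  "both",
                  ifelse(band$unbounded_upper[off], "upper", "lower"))
  )
  structure(list(status = if (any(off)) "non_observable" else "observable",
                 state = attr(band, "state"), alpha = attr(band, "alpha"),
                 detail = detail),
            class = "observability")
}

#' @export
print.observability <- function(x, ...) {
  cat("<observability> ", x$state, ": ", x$status,
      " (alpha = ", x$alpha, ")\n", sep = "")
  if (nrow(x$detail)) {
    cat("  unbounded at:\n")
    print(x$detail)
  }
  invisible(x)
}

#' Monte-Carlo coverage study for prediction or validation intervals
#'
#' Verifies the defining frequency property of the intervals: across
#' repeated noise realizations, the interval should contain the model
#' response at the true parameters (prediction mode) -- or an independently
#' drawn noisy validation measurement (validation mode) -- with probability
#' alpha.  Each replicate simulates fresh data at `theta_true`, refits the
#' model (warm-started near the truth, with a multi-start fallback when the
#' fit looks poor), profiles the prediction and tests membership.
#' Replicates are driven by per-replicate seeds derived from the master
#' seed, so the study is reproducible as a whole and per replicate.
#'
#' @param model An [ode_model()].
#' @param theta_true True (data-generating) parameter vector.
#' @param design An [experimental_design()] for the simulated data.
#' @param target A [prediction_target()].
#' @param alpha Confidence level.
#' @param n_reps Number of replicates (>= 50).
#' @param seed Master seed.
#' @param mode `"prediction"` or `"validation"`.
#' @param sd Validation measurement error (validation mode).
#' @param sigma Measurement noise of the simulated data (default: the
#'   model's declared `noise_sd`).
#' @param scan A [scan_config()].
#' @param n_starts_fallback Multi-start size used when the warm-started
#'   replicate fit is implausibly poor.
#' @return An object of class `coverage_result` with the hit frequency, an
#'   exact binomial 95% confidence interval, and the failure count.
#'   Replicate-level failures are excluded from the frequency; if more than
#'   10% fail the study is marked invalid.
#' @export
coverage_study <- function(model, theta_true, design, target, alpha = 0.9,
                           n_reps = 200L, seed = 1L,
                           mode = c("prediction", "validation"), sd = NULL,
                           sigma = NULL, scan = scan_config(),
                           n_starts_fallback = 8L) {
  mode <- match.arg(mode)
  if (n_reps < 50L) stop_config("n_reps must be >= 50")
  if (mode == "validation" && (!is_scalar_number(sd) || sd <= 0))
    stop_config("validation mode needs a positive 'sd'")
  theta_true <- resolve_theta(model, theta_true)
  z_true <- stats::predict(model, theta_true, target)
  threshold <- profile_threshold(alpha)
  p <- length(theta_true)
  n_pts <- length(design$times) * length(design$observables)
  # plausible -2LL* for a healthy fit: chi-square-ish in the data size
  dev_cap <- n_pts + 6 * sqrt(2 * n_pts)
  rep_seeds <- with_seed(seed, sample.int(2147483646L, n_reps))

  hits <- rep(NA, n_reps)
  for (r in seq_len(n_reps)) {
    hits[r] <- tryCatch(with_seed(rep_seeds[r], {
      dat <- simulate_dataset(model, theta_true, design,
                              noise_spec(sigma = sigma, seed = NULL))
      z_val <- if (mode == "validation") stats::rnorm(1, z_true, sd)
      start <- theta_true * exp(stats::rnorm(p, 0, 0.05))
      f <- fit_model(model, dat, n_starts = 1L, seed = rep_seeds[r],
                     start = start)
      if (f$neg2LL_star > dev_cap)
        f <- fit_model(model, dat, n_starts = n_starts_fallback,
                       seed = rep_seeds[r], start = start)
      curve <- if (mode == "prediction")
        ppl_scan(model, dat, target, f, scan = scan, alpha = alpha)
      else
        vpl_scan(model, dat, validation_setup(target, sd), f, scan = scan,
                 alpha = alpha)
      ci <- interval_from_curve(curve, threshold, alpha)
      zq <- if (mode == "prediction") z_true else z_val
      lo <- if (ci$unbounded_lower) -Inf else ci$lower
      hi <- if (ci$unbounded_upper) Inf else ci$upper
      zq >= lo && zq <= hi
    }), error = function(e) NA)
  }
  n_fail <- sum(is.na(hits))
  n_ok <- n_reps - n_fail
  n_hit <- sum(hits, na.rm = TRUE)
  bt <- if (n_ok > 0) stats::binom.test(n_hit, n_ok)$conf.int else c(NA, NA)
  structure(list(n_reps = as.integer(n_reps), n_ok = n_ok, n_hit = n_hit,
                 n_fail = n_fail, coverage = n_hit / n_ok,
                 alpha = alpha, binomial_ci = as.numeric(bt),
                 mode = mode, seed = as.integer(seed),
                 valid = n_fail <= 0.1 * n_reps),
            class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat("<coverage_result> ", x$mode, " mode: ", x$n_hit, "/", x$n_ok,
      " hits = ", format(round(x$coverage, 4)), " (nominal ", x$alpha,
      "), 95% binomial CI [", format(round(x$binomial_ci[1], 4)), ", ",
      format(round(x$binomial_ci[2], 4)), "]\n", sep = "")
  if (x$n_fail) cat("  ", x$n_fail, " failed replicate(s) excluded",
                    if (!x$valid) " -- STUDY INVALID (>10% failures)",
                    "\n", sep = "")
  invisible(x)
}

#' Rank experimental conditions by prediction uncertainty
#'
#' Conditions with wide prediction confidence intervals are weakly
#' specified by the existing data; measuring them is the most informative
#' next experiment.  All (state, time) entries of the given bands are
#' sorted by descending interval width; unbounded entries rank first with
#' infinite width, ties break deterministically by (state, time).
#'
#' @param bands A list of [pci_band()] results computed at the same alpha.
#' @return `data.frame` with columns `state`, `time`, `width`, ordered by
#'   descending width; class `design_ranking`.
#' @export
design_ranking <- function(bands) {
  if (inherits(bands, "confidence_band")) bands <- list(bands)
  alphas <- vapply(bands, function(b) attr(b, "alpha"), numeric(1))
  if (length(unique(alphas)) != 1L)
    stop_config("all bands must share the same alpha")
  tab <- do.call(rbind, lapply(bands, function(b) {
    width <- ifelse(b$unbounded_lower | b$unbounded_upper, Inf,
                    b$upper - b$lower)
    data.frame(state = attr(b, "state"), time = b$time, width = width)
  }))
  tab <- tab[order(-tab$width, tab$state, tab$time), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("design_ranking", "data.frame")
  tab
}
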