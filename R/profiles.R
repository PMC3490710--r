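# Model response F(t_i, u_i, theta) at every record of a dataset.
model_response <- function(model, theta, data) {
  obj <- make_objective(model, data)
  theta <- resolve_theta(model, theta)
  val <- obj$value(log(theta[obj$free]), raise = TRUE)
  data$value - val$res[seq_len(nrow(data))] * data$sigma
}

# inner re-optimization along a scan is warm-started, so modest iteration
# caps suffice; crossing accuracy comes from the root-finding refinement
scan_ctrl <- function() minpack.lm::nls.lm.control(maxiter = 50L,
                                                   ftol = 1e-11, ptol = 1e-9)

phi_at_bound <- function(par, lb, ub, tol = 1e-6) {
  any(par - lb < tol | ub - par < tol)
}

# Problem scale of a prediction scan.  Anchored on the spread of the data
# (the units the model is specified in), not on the fitted prediction: with
# a practically non-identifiable concentration dimension the fitted
# prediction can sit at an arbitrary point of the flat manifold, and a
# scale derived from it would defeat the plausibility range that flags
# unbounded intervals.
prediction_scale <- function(z_hat, data, extra = 0) {
  span <- diff(range(data$value))
  max(0.5 * span, extra, 1e-6)
}

# Augmented-Lagrangian solution of
#   min_theta RSS(theta | y)  s.t.  F(D_pred, theta) = z
# built on successive penalized least-squares solves; the penalty residual
# sqrt(mu) (F - z) + lambda / (2 sqrt(mu)) squares to the augmented
# Lagrangian up to a constant.
al_eval <- function(obj, z, warm, lb, ub, ctrl, scale,
                    ctol = NULL, max_outer = 12L) {
  ctol <- ctol %||% max(1e-8 * scale, 1e-12)
  lambda <- 0
  mu <- 1 / (0.01 * scale)^2
  c_prev <- Inf
  par <- inward(warm, lb, ub)
  val <- NULL
  for (k in seq_len(max_outer)) {
    pen <- list(w = sqrt(mu), z = z, s = lambda / (2 * sqrt(mu)))
    r <- tryCatch(suppressWarnings(minpack.lm::nls.lm(par = par, lower = lb, upper = ub,
                                     fn = obj$fn, control = ctrl, pen = pen)),
                  error = function(e) NULL)
    if (is.null(r)) return(list(ok = FALSE))
    par <- r$par
    val <- obj$value(par, pen = pen)
    cc <- val$F_pred - z
    if (!is.finite(cc)) return(list(ok = FALSE))
    if (abs(cc) < ctol) break
    if (abs(cc) > 0.5 * abs(c_prev)) mu <- mu * 10 else lambda <- lambda + 2 * mu * cc
    c_prev <- cc
    if (mu > 1e16 / scale^2) break
  }
  feasible <- abs(val$F_pred - z) < 100 * ctol
  list(ok = TRUE, value = val$rss_data, zprime = val$F_pred,
       warm = par, feasible = feasible)
}

#' Validation profile likelihood scan
#'
#' Profiles the joint likelihood of the observed data and one hypothetical
#' noisy validation measurement z with known error `sd`: for each scanned z
#' the parameters are re-optimized on the objective
#' RSS(data) + (z - F(D_vali, theta))^2 / sd^2, warm-started from the
#' neighboring grid point.  Thresholding the resulting curve gives the
#' validation confidence interval -- the interval that a future measurement
#' with error `sd` must hit for the model not to be rejected.  The fitted
#' model response z' at every grid point is recorded so the curve can be
#' rescaled to a prediction profile ([rescale_vpl_to_ppl()]).
#'
#' @param model An [ode_model()].
#' @param data Dataset `data.frame` the fit was based on.
#' @param setup A [validation_setup()] (target plus measurement error SD).
#' @param fit A [fit_model()] result.
#' @param scan A [scan_config()].
#' @param alpha Confidence level the scan should resolve (stop level and
#'   crossing refinement).
#' @return A [profile_curve()] of kind `"validation"`.  If more than 20% of
#'   the attempted grid points failed to optimize, attribute
#'   `"unreliable"` is set to `TRUE`.
#' @export
vpl_scan <- function(model, data, setup, fit, scan = scan_config(),
                     alpha = 0.9) {
  stopifnot(inherits(setup, "validation_setup"), inherits(fit, "ppl_fit"))
  target <- setup$target
  SD <- setup$sd
  obj <- make_objective(model, data, pred = target, fixed = fit$fixed)
  lb <- log(fit$bounds$lower); ub <- log(fit$bounds$upper)
  ctrl <- scan_ctrl()
  v0 <- obj$value(fit$phi_hat)
  if (!v0$ok) stop_config("model cannot be integrated at the fitted optimum")
  z_hat <- v0$F_pred
  f0 <- v0$rss_data
  threshold <- profile_threshold(alpha)
  scale <- prediction_scale(z_hat, data, extra = SD)

  n_try <- 0L; n_bad <- 0L
  eval_fn <- function(z, warm) {
    n_try <<- n_try + 1L
    pen <- list(w = 1 / SD, z = z)
    r <- tryCatch(suppressWarnings(minpack.lm::nls.lm(par = inward(warm, lb, ub),
                                     lower = lb, upper = ub,
                                     fn = obj$fn, control = ctrl, pen = pen)),
                  error = function(e) NULL)
    if (is.null(r)) { n_bad <<- n_bad + 1L; return(list(ok = FALSE)) }
    val <- obj$value(r$par, pen = pen)
    if (!val$ok) { n_bad <<- n_bad + 1L; return(list(ok = FALSE)) }
    list(ok = TRUE, value = val$rss_total, grid = z,
         pen = (val$F_pred - z)^2 / SD^2, warm = r$par,
         at_bound = phi_at_bound(r$par, lb, ub),
         extra = c(zprime = val$F_pred))
  }

  res <- scan_profile(eval_fn, z0 = z_hat, f0 = f0, warm0 = fit$phi_hat,
                      threshold = threshold, scan = scan, scale = scale,
                      pen_infeasibility = FALSE,
                      extra0 = c(zprime = z_hat))
  curve <- profile_curve(res$points$grid, res$points$value, neg2LL_star = f0,
                         kind = "validation", sides = res$sides,
                         extra = data.frame(zprime = res$points$zprime,
                                            scan_z = res$points$scan_z),
                         alpha = alpha, scale = scale)
  attr(curve, "sd") <- SD
  attr(curve, "unreliable") <- n_try > 0L && n_bad / n_try > 0.2
  curve
}

#' Prediction profile likelihood scan
#'
#' Profiles the data likelihood under the constraint that the model
#' prediction equals a scanned value z:
#' PPL(z) = max over theta with F(D_pred, theta) = z of LL(y | theta).
#' Thresholding at the chi-square(1) quantile yields the prediction
#' confidence interval; a side whose profile stays flat below the threshold
#' signals practical non-observability of the predicted quantity.
#'
#' The default `"penalized"` method relaxes the constraint to a quadratic
#' penalty with a small standard deviation (`constraint_sd_fraction` of the
#' prediction scale) and rescales the resulting validation-type profile
#' back to the exact prediction profile via the identity
#' -2 PPL(z') = -2 VPL(z) - (z' - z)^2 / SD^2 with z' the fitted model
#' response, avoiding hard constrained optimization.  The `"constrained"`
#' method enforces the constraint directly by an augmented-Lagrangian loop
#' and serves as an independent cross-check; scanned values the model
#' cannot attain (e.g. negative concentrations) are reported as the
#' feasibility boundary of the interval, not as unboundedness.
#'
#' @param model An [ode_model()].
#' @param data Dataset `data.frame` the fit was based on.
#' @param target A [prediction_target()].
#' @param fit A [fit_model()] result.
#' @param scan A [scan_config()].
#' @param method `"penalized"` (default) or `"constrained"`.
#' @param alpha Confidence level the scan should resolve.
#' @return A [profile_curve()] of kind `"prediction"` over the prediction
#'   value; for the penalized method the abscissa is the recorded fitted
#'   response z'.
#' @export
ppl_scan <- function(model, data, target, fit, scan = scan_config(),
                     method = c("penalized", "constrained"), alpha = 0.9) {
  stopifnot(inherits(target, "prediction_target"), inherits(fit, "ppl_fit"))
  method <- match.arg(method)
  obj <- make_objective(model, data, pred = target, fixed = fit$fixed)
  lb <- log(fit$bounds$lower); ub <- log(fit$bounds$upper)
  ctrl <- scan_ctrl()
  v0 <- obj$value(fit$phi_hat)
  if (!v0$ok) stop_config("model cannot be integrated at the fitted optimum")
  z_hat <- v0$F_pred
  f0 <- v0$rss_data
  threshold <- profile_threshold(alpha)
  scale <- prediction_scale(z_hat, data)

  n_try <- 0L; n_bad <- 0L
  if (method == "penalized") {
    # penalty SD: small relative to the larger of the fitted prediction
    # magnitude and the data scale, so the rescaling correction stays
    # numerically benign without making the penalty ill-conditioned
    SDc <- scan$constraint_sd_fraction * max(abs(z_hat), scale)
    pen_cap <- scan$feasibility_pen_factor *
      (threshold + scan$threshold_margin)
    eval_fn <- function(z, warm) {
      n_try <<- n_try + 1L
      pen <- list(w = 1 / SDc, z = z)
      solve_from <- function(par0) {
        tryCatch(suppressWarnings(minpack.lm::nls.lm(par = inward(par0, lb, ub),
                                    lower = lb, upper = ub,
                                    fn = obj$fn, control = ctrl, pen = pen)),
                 error = function(e) NULL)
      }
      r <- solve_from(warm)
      val <- if (!is.null(r)) obj$value(r$par, pen = pen)
      # a large unmet penalty can mean the optimizer stalled (maxiter,
      # ill-conditioned step) rather than a real boundary: restart from the
      # stall point and from the global optimum before believing it
      for (par0 in list(if (!is.null(r)) r$par, fit$phi_hat)) {
        if (!is.null(val) && val$ok &&
            (val$F_pred - z)^2 / SDc^2 <= pen_cap) break
        if (is.null(par0)) next
        r2 <- solve_from(par0)
        if (!is.null(r2) && (is.null(r) || r2$deviance < r$deviance)) {
          r <- r2
          val <- obj$value(r$par, pen = pen)
        }
      }
      if (is.null(r) || is.null(val)) { n_bad <<- n_bad + 1L; return(list(ok = FALSE)) }
      if (!val$ok) { n_bad <<- n_bad + 1L; return(list(ok = FALSE)) }
      # rescaling identity: the data-only RSS at the penalized optimum IS
      # the prediction profile value at z' = F(theta*)
      list(ok = TRUE, value = val$rss_data, grid = val$F_pred,
           pen = (val$F_pred - z)^2 / SDc^2, warm = r$par,
           at_bound = phi_at_bound(r$par, lb, ub),
           extra = c(vpl = val$rss_total))
    }
    res <- scan_profile(eval_fn, z0 = z_hat, f0 = f0, warm0 = fit$phi_hat,
                        threshold = threshold, scan = scan, scale = scale,
                        pen_infeasibility = TRUE, extra0 = c(vpl = f0))
    extra <- data.frame(vpl = res$points$vpl, scan_z = res$points$scan_z)
  } else {
    eval_fn <- function(z, warm) {
      n_try <<- n_try + 1L
      r <- al_eval(obj, z, warm, lb, ub, ctrl, max(abs(z_hat), scale))
      if (!isTRUE(r$ok)) { n_bad <<- n_bad + 1L; return(list(ok = FALSE)) }
      # an unattainable z terminates the side at the feasibility boundary:
      # report the closest attainable response, not the requested value
      list(ok = TRUE, value = r$value,
           grid = if (r$feasible) z else r$zprime,
           pen = 0, warm = r$warm,
           at_bound = phi_at_bound(r$warm, lb, ub),
           infeasible = !r$feasible, extra = c(zprime = r$zprime))
    }
    res <- scan_profile(eval_fn, z0 = z_hat, f0 = f0, warm0 = fit$phi_hat,
                        threshold = threshold, scan = scan, scale = scale,
                        pen_infeasibility = FALSE, extra0 = c(zprime = z_hat))
    extra <- data.frame(zprime = res$points$zprime, scan_z = res$points$scan_z)
  }
  curve <- profile_curve(res$points$grid, res$points$value, neg2LL_star = f0,
                         kind = "prediction", sides = res$sides,
                         extra = extra, alpha = alpha, scale = scale)
  attr(curve, "method") <- method
  attr(curve, "unreliable") <- n_try > 0L && n_bad / n_try > 0.2
  curve
}

#' Rescale a validation profile to a prediction profile
#'
#' Applies the identity -2 PPL(z') = -2 VPL(z) - (z' - z)^2 / SD^2, where
#' z' = F(D_vali, theta*(z, y)) is the fitted model response recorded at
#' each point of the validation scan.  At the optimum z = z' the correction
#' vanishes and PPL = VPL.  The returned curve has kind `"prediction"` and
#' the recorded z' as abscissa.  A side whose endpoint carried a
#' non-negligible correction is marked `"truncated"` (its prediction-scale
#' crossing lies beyond the scanned range) and is treated as unbounded by
#' [interval_from_curve()]; for interval construction prefer
#' [ppl_scan()], whose stopping rules operate on the rescaled values
#' directly.
#'
#' @param curve A [profile_curve()] of kind `"validation"` with recorded
#'   `zprime` (as produced by [vpl_scan()]).
#' @param sd The validation measurement error used in the scan (defaults to
#'   the value stored on the curve).
#' @return A [profile_curve()] of kind `"prediction"`.
#' @export
rescale_vpl_to_ppl <- function(curve, sd = attr(curve, "sd")) {
  stopifnot(inherits(curve, "profile_curve"))
  if (curve$kind != "validation")
    stop_config("rescaling requires a validation-kind curve")
  if (is.null(curve$extra) || is.null(curve$extra$zprime))
    stop_config("curve carries no recorded fitted responses z'; ",
                "it was not produced by vpl_scan()")
  if (!is_scalar_number(sd) || sd <= 0) stop_config("'sd' must be > 0")
  zp <- curve$extra$zprime
  pen <- (curve$grid - zp)^2 / sd^2
  vals <- curve$neg2PL - pen
  sides <- curve$sides
  for (side in c("left", "right")) {
    i_end <- if (side == "left") which.min(zp) else which.max(zp)
    if (pen[i_end] > 0.05) {
      sides[[side]]$reason <- "truncated"
      sides[[side]]$crossed <- FALSE
    }
  }
  out <- profile_curve(zp, vals, neg2LL_star = curve$neg2LL_star,
                       kind = "prediction", sides = sides,
                       extra = data.frame(scan_z = curve$grid,
                                          vpl = curve$neg2PL),
                       alpha = curve$alpha, scale = curve$scale)
  attr(out, "method") <- "rescaled"
  out
}

#' Confidence threshold for profile-likelihood intervals
#'
#' The asymptotic threshold is the alpha quantile of the chi-square
#' distribution with one degree of freedom (the likelihood-ratio statistic
#' of a single profiled quantity).  When the asymptotic assumption is in
#' doubt, a Monte-Carlo threshold can be computed by parametric bootstrap:
#' data are re-simulated at the fitted parameters, each replicate is
#' refitted, and the profile test statistic
#' -2 (PPL(z_gen) - LL*) -- with z_gen the generating prediction --
#' is evaluated by constrained optimization; the empirical alpha quantile
#' of these statistics replaces the chi-square quantile.
#'
#' @param alpha Confidence level in (0, 1).
#' @param method `"asymptotic"` (default) or `"montecarlo"`.
#' @param model,data,fit,target Required for the Monte-Carlo method: the
#'   model, the observed dataset, its [fit_model()] result and the
#'   [prediction_target()] whose profile the threshold is for.
#' @param n_reps Bootstrap replicates (>= 100; fewer makes the quantile too
#'   unstable and is refused).
#' @param seed Integer seed for the bootstrap.
#' @return The threshold on the -2 log-likelihood scale.  For the
#'   Monte-Carlo method, attributes `"n_used"` and `"se"` (quantile
#'   standard error estimate) are attached.
#' @export
profile_threshold <- function(alpha, method = c("asymptotic", "montecarlo"),
                              model = NULL, data = NULL, fit = NULL,
                              target = NULL, n_reps = 500L, seed = 1L) {
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1)
    stop_config("alpha must be in (0, 1)")
  method <- match.arg(method)
  if (method == "asymptotic") return(stats::qchisq(alpha, df = 1))
  if (n_reps < 100L)
    stop_config("Monte-Carlo threshold needs at least 100 replicates")
  if (is.null(model) || is.null(data) || is.null(fit) || is.null(target))
    stop_config("Monte-Carlo threshold needs model, data, fit and target")

  theta_hat <- fit$theta_hat
  Fbar <- model_response(model, theta_hat, data)
  z_gen <- stats::predict(model, theta_hat, target)
  lb <- log(fit$bounds$lower); ub <- log(fit$bounds$upper)
  ctrl <- scan_ctrl()
  scale <- prediction_scale(z_gen, data)
  p <- length(fit$free)
  rep_seeds <- with_seed(seed, sample.int(2147483646L, n_reps))
  stats_v <- rep(NA_real_, n_reps)
  for (r in seq_len(n_reps)) {
    stats_v[r] <- tryCatch(with_seed(rep_seeds[r], {
      d2 <- data
      d2$value <- Fbar + stats::rnorm(nrow(data)) * d2$sigma
      start <- theta_hat[fit$free] * exp(stats::rnorm(p, 0, 0.05))
      f2 <- fit_model(model, d2, n_starts = 1L, seed = rep_seeds[r],
                      start = start, bounds = fit$bounds, fixed = fit$fixed)
      obj2 <- make_objective(model, d2, pred = target, fixed = fit$fixed)
      con <- al_eval(obj2, z_gen, f2$phi_hat, lb, ub, ctrl,
                     max(abs(z_gen), scale))
      if (!isTRUE(con$ok) || !con$feasible) NA_real_
      else max(0, con$value - f2$neg2LL_star)
    }), error = function(e) NA_real_)
  }
  used <- stats_v[is.finite(stats_v)]
  if (length(used) < 100L)
    stop_config("too few successful bootstrap replicates (",
                length(used), ")")
  thr <- as.numeric(stats::quantile(used, alpha, type = 8))
  dens <- stats::density(used, from = thr, to = thr, n = 1L)$y
  attr(thr, "n_used") <- length(used)
  attr(thr, "se") <- sqrt(alpha * (1 - alpha) / length(used)) /
    max(dens, .Machine$double.eps)
  thr
}
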