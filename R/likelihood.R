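# Builds the weighted least-squares objective shared by fitting and all
# profile scans.  Residuals are standardized, so the objective deviance is
# the -2 log-likelihood up to its constant offset (i.e. the RSS).  An
# optional prediction term (expr, time, input) is integrated alongside the
# data so a quadratic penalty (z - F)^2 / SD^2 can be appended; optimization
# runs on log-parameters to enforce positivity of rates and concentrations.
make_objective <- function(model, data, pred = NULL, fixed = NULL) {
  validate_dataset(model, data)
  pn <- names(model$parameters)
  fixed <- fixed %||% stats::setNames(numeric(0), character(0))
  if (length(fixed)) {
    bad <- setdiff(names(fixed), pn)
    if (length(bad)) stop_config("unknown fixed parameter(s): ",
                                 paste(bad, collapse = ", "))
  }
  free <- setdiff(pn, names(fixed))

  rec_input <- if (!is.null(data$input)) as.character(data$input)
               else rep(dataset_input(data), nrow(data))
  conds <- unique(c(rec_input, if (!is.null(pred)) pred$input))

  # per-condition precomputation: union time grid, record -> (time, expr)
  # index maps, compiled observable expressions, input bindings
  setup <- lapply(conds, function(cn) {
    rid <- which(rec_input == cn)
    t_extra <- if (!is.null(pred) && pred$input == cn) pred$time else numeric(0)
    tt <- sort(unique(c(0, data$time[rid], t_extra)))
    onames <- unique(data$observable[rid])
    exprs <- lapply(onames, function(o) target_expr(model, o))
    names(exprs) <- onames
    cond <- model$inputs[[cn]]
    if (is.null(cond)) stop_config("unknown input condition '", cn, "'")
    in_bind <- lapply(model$input_vars, function(iv) {
      v <- cond[[iv]]
      if (is.data.frame(v))
        stats::approxfun(v$time, v$value, method = "constant", rule = 2)(tt)
      else as.numeric(v)
    })
    names(in_bind) <- model$input_vars
    list(name = cn, rid = rid, tt = tt,
         it = match(data$time[rid], tt), exprs = exprs,
         obs = data$observable[rid], in_bind = in_bind,
         pred_it = if (length(t_extra)) match(pred$time, tt) else NA_integer_)
  })
  pred_expr <- if (!is.null(pred)) target_expr(model, pred$observable)
  n_data <- nrow(data)
  counters <- new.env(parent = emptyenv())
  counters$n_eval <- 0L
  counters$n_fail <- 0L

  value <- function(phi, pen = NULL, raise = FALSE, fixed_override = NULL) {
    counters$n_eval <- counters$n_eval + 1L
    theta <- model$parameters
    theta[free] <- exp(phi)
    if (length(fixed)) theta[names(fixed)] <- fixed
    if (!is.null(fixed_override)) theta[names(fixed_override)] <- fixed_override
    res <- numeric(n_data)
    F_pred <- NA_real_
    for (s in setup) {
      traj <- tryCatch(integrate_model(model, theta, s$tt, input = s$name),
                       error = function(e) if (raise) stop(e) else NULL)
      if (is.null(traj)) {
        counters$n_fail <- counters$n_fail + 1L
        return(list(ok = FALSE,
                    res = rep(1e4, n_data + as.integer(!is.null(pen)))))
      }
      env <- as.list(theta)
      for (j in seq_along(model$states)) env[[model$states[j]]] <- traj$states[, j]
      env$t <- s$tt
      env[model$input_vars] <- s$in_bind
      for (o in names(s$exprs)) {
        go <- rep_len(as.numeric(eval(s$exprs[[o]], env)), length(s$tt))
        sel <- which(s$obs == o)
        res[s$rid[sel]] <- (data$value[s$rid[sel]] - go[s$it[sel]]) /
          data$sigma[s$rid[sel]]
      }
      if (!is.na(s$pred_it)) {
        gp <- rep_len(as.numeric(eval(pred_expr, env)), length(s$tt))
        F_pred <- gp[s$pred_it]
      }
    }
    if (!is.null(pen))
      res <- c(res, pen$w * (F_pred - pen$z) + (pen$s %||% 0))
    list(ok = TRUE, res = res, rss_data = sum(res[seq_len(n_data)]^2),
         rss_total = sum(res^2), F_pred = F_pred)
  }

  fn <- function(phi, pen = NULL, fixed_override = NULL)
    value(phi, pen, fixed_override = fixed_override)$res

  list(fn = fn, value = value, free = free, fixed = fixed,
       counters = counters, n_data = n_data)
}

#' -2 log-likelihood (weighted residual sum of squares)
#'
#' For additive Gaussian noise with known sigma, minus two times the
#' log-likelihood equals, up to an additive constant that is dropped
#' throughout the package, the standardized residual sum of squares
#' \eqn{\sum_i (y_i - F(t_i, u, \theta))^2 / \sigma_i^2}.  All thresholds
#' used for confidence intervals are differences of this quantity, so the
#' dropped constant never matters.
#'
#' @param model An [ode_model()].
#' @param theta Parameter vector (positive).
#' @param data Dataset `data.frame` (`time`, `observable`, `value`,
#'   `sigma`).
#' @return Non-negative scalar.  Integration failure is raised as a
#'   `pplik_integration_error`.
#' @export
neg2_loglik <- function(model, theta, data) {
  theta <- resolve_theta(model, theta)
  if (any(theta <= 0)) stop_config("parameters must be positive")
  obj <- make_objective(model, data)
  obj$value(log(theta[obj$free]), raise = TRUE)$rss_data
}

default_bounds <- function(model, free, factor = 100) {
  d <- model$parameters[free]
  list(lower = d / factor, upper = d * factor)
}

resolve_bounds <- function(model, bounds, free, factor = 100) {
  if (is.null(bounds)) return(default_bounds(model, free, factor))
  lo <- bounds$lower; up <- bounds$upper
  if (is.null(names(lo))) names(lo) <- free
  if (is.null(names(up))) names(up) <- free
  lo <- lo[free]; up <- up[free]
  if (any(is.na(lo)) || any(is.na(up)))
    stop_config("bounds must cover all free parameters")
  if (any(lo <= 0) || any(up <= lo))
    stop_config("need 0 < lower < upper bounds")
  list(lower = lo, upper = up)
}

#' Maximum-likelihood fit by multi-start least squares
#'
#' Minimizes the standardized residual sum of squares (equivalently,
#' maximizes the Gaussian likelihood) with the Levenberg-Marquardt
#' algorithm, run from multiple starting points: the model's default
#' parameters (or `start`) plus Latin-hypercube draws in log-parameter
#' space inside the bounds box.  Deterministic for a given `seed`.
#'
#' @param model An [ode_model()].
#' @param data Dataset `data.frame`.
#' @param n_starts Number of starts (>= 1).
#' @param seed Integer seed for the start draws (mandatory for
#'   reproducibility).
#' @param bounds `list(lower, upper)` named per free parameter on the
#'   natural scale; default is a box spanning four orders of magnitude
#'   around the model's default values.
#' @param start Optional named start vector (natural scale) used as the
#'   first start.
#' @param fixed Optional named vector of parameters held fixed (natural
#'   scale).
#' @param control A [minpack.lm::nls.lm.control()] list.
#' @return An object of class `ppl_fit` with `theta_hat` (natural scale,
#'   including fixed entries), `neg2LL_star`, `n_starts`,
#'   `converged_fraction` and `seed`.  Errors if every start fails, with
#'   per-start diagnostics.
#' @export
fit_model <- function(model, data, n_starts = 20L, seed = 1L, bounds = NULL,
                      start = NULL, fixed = NULL, control = NULL) {
  if (n_starts < 1L) stop_config("n_starts must be >= 1")
  obj <- make_objective(model, data, fixed = fixed)
  free <- obj$free
  p <- length(free)
  if (!p) stop_config("no free parameters to fit")
  bounds <- resolve_bounds(model, bounds, free)
  lb <- log(bounds$lower); ub <- log(bounds$upper)
  ctrl <- control %||% minpack.lm::nls.lm.control(maxiter = 200L,
                                                  ftol = 1e-12, ptol = 1e-10)
  s1 <- if (is.null(start)) model$parameters[free] else resolve_theta(model, start)[free]
  starts <- matrix(clamp(log(s1), lb, ub), nrow = 1L)
  if (n_starts > 1L) {
    u <- with_seed(seed, lhs::randomLHS(n_starts - 1L, p))
    starts <- rbind(starts, sweep(u, 2L, ub - lb, `*`) +
                              matrix(lb, n_starts - 1L, p, byrow = TRUE))
  }
  run_one <- function(par0) {
    # restart Levenberg-Marquardt from its own solution until the deviance
    # stops improving; guards against premature step-size termination on
    # ill-conditioned problems
    r <- suppressWarnings(
      minpack.lm::nls.lm(par = inward(par0, lb, ub), lower = lb,
                         upper = ub, fn = obj$fn, control = ctrl))
    for (k in 1:2) {
      r2 <- suppressWarnings(
        minpack.lm::nls.lm(par = inward(r$par, lb, ub), lower = lb,
                           upper = ub, fn = obj$fn, control = ctrl))
      impr <- r$deviance - r2$deviance
      if (r2$deviance < r$deviance) r <- r2
      if (impr < 1e-9 * (1 + abs(r$deviance))) break
    }
    r
  }
  runs <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    runs[[i]] <- tryCatch(run_one(starts[i, ]), error = function(e) e)
  }
  ok <- !vapply(runs, inherits, logical(1), "error")
  if (!any(ok)) {
    msgs <- vapply(runs, conditionMessage, character(1))
    stop_config("all ", n_starts, " fitting starts failed: ",
                paste(unique(msgs), collapse = " | "))
  }
  dev <- vapply(runs, function(r) if (inherits(r, "error")) Inf else r$deviance,
                numeric(1))
  best <- runs[[which.min(dev)]]
  info <- vapply(runs[ok], function(r) r$info, numeric(1))
  phi_hat <- best$par
  theta_hat <- model$parameters
  theta_hat[free] <- exp(phi_hat)
  if (length(obj$fixed)) theta_hat[names(obj$fixed)] <- obj$fixed
  structure(list(theta_hat = theta_hat,
                 phi_hat = stats::setNames(phi_hat, free),
                 neg2LL_star = best$deviance,
                 n_starts = as.integer(n_starts),
                 converged_fraction = mean(info %in% 1:3),
                 seed = as.integer(seed),
                 bounds = bounds, fixed = obj$fixed, free = free,
                 model = model$name,
                 start_deviances = dev),
            class = "ppl_fit")
}

#' @export
print.ppl_fit <- function(x, ...) {
  cat("<ppl_fit> model ", x$model, ": -2LL* = ", format(x$neg2LL_star),
      " (", x$n_starts, " starts, ",
      round(100 * x$converged_fraction), "% converged)\n", sep = "")
  print(x$theta_hat)
  invisible(x)
}

#' Parameter profile likelihood and likelihood-based confidence interval
#'
#' Scans one parameter over a grid while re-optimizing all remaining
#' parameters at every grid point (profile likelihood), and thresholds the
#' profile at the chi-square(1) quantile to obtain the likelihood-based
#' confidence interval.  A practically non-identifiable parameter produces
#' a profile that stays below the threshold in some direction; that side is
#' flagged unbounded rather than raising an error.
#'
#' @param model An [ode_model()].
#' @param data Dataset `data.frame` used for `fit`.
#' @param fit A [fit_model()] result.
#' @param param Parameter name or index.
#' @param alpha Confidence level in (0, 1).
#' @param scan A [scan_config()].
#' @return List with `curve` (a [profile_curve()]) and `ci` (a
#'   `profile_ci`).
#' @export
profile_parameter <- function(model, data, fit, param, alpha = 0.9,
                              scan = scan_config()) {
  stopifnot(inherits(fit, "ppl_fit"))
  free <- fit$free
  if (is.numeric(param)) param <- free[param]
  if (!param %in% free) stop_config("'", param, "' is not a free fitted parameter")
  others <- setdiff(free, param)
  threshold <- profile_threshold(alpha)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 150L, ftol = 1e-12, ptol = 1e-10)
  lb <- log(fit$bounds$lower); ub <- log(fit$bounds$upper)

  obj <- make_objective(model, data,
                        fixed = c(fit$fixed,
                                  stats::setNames(fit$theta_hat[[param]], param)))
  eval_fn <- function(v, warm) {
    ov <- stats::setNames(v, param)
    if (length(others)) {
      r <- tryCatch(suppressWarnings(minpack.lm::nls.lm(par = warm, lower = lb[others],
                                       upper = ub[others], fn = obj$fn,
                                       control = ctrl, fixed_override = ov)),
                    error = function(e) NULL)
      if (is.null(r)) return(list(ok = FALSE))
      list(ok = TRUE, value = r$deviance, warm = r$par, pen = 0)
    } else {
      val <- obj$value(numeric(0), fixed_override = ov)
      if (!val$ok) return(list(ok = FALSE))
      list(ok = TRUE, value = val$rss_data, warm = warm, pen = 0)
    }
  }

  z0 <- fit$theta_hat[[param]]
  warm0 <- fit$phi_hat[others]
  res <- scan_profile(eval_fn, z0 = z0, f0 = fit$neg2LL_star, warm0 = warm0,
                      threshold = threshold, scan = scan,
                      scale = max(abs(z0), 1e-8),
                      lower = fit$bounds$lower[[param]],
                      upper = fit$bounds$upper[[param]])
  curve <- profile_curve(res$points$grid, res$points$value,
                         neg2LL_star = fit$neg2LL_star, kind = "parameter",
                         sides = res$sides, alpha = alpha,
                         scale = max(abs(z0), 1e-8))
  list(curve = curve,
       ci = interval_from_curve(curve, threshold, alpha))
}
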