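#' Configure a profile-likelihood scan
#'
#' Controls the adaptive outward march used by all profile scans.  Starting
#' from the fitted optimum, each side is stepped outward with a step size
#' adapted so that the increase of the -2 log profile likelihood per step is
#' about `step_fraction` times the confidence threshold, until the profile
#' exceeds the threshold plus `threshold_margin`, the scan leaves the
#' plausibility range (`max_range_factor` times the problem scale), the
#' constraint becomes infeasible, or `max_steps_per_side` is exhausted.
#' Sides that end without crossing are flagged, which is the operational
#' signal for unbounded confidence intervals (non-observability).
#'
#' @param step_fraction Target increase of -2 log-likelihood per step, as a
#'   fraction of the chi-square threshold.
#' @param max_steps_per_side Maximum number of grid points per side (>= 10).
#' @param threshold_margin Extra -2 log-likelihood margin scanned beyond the
#'   threshold so the crossing is safely bracketed.
#' @param constraint_sd_fraction Penalty standard deviation used by the
#'   penalized prediction profile, as a fraction of the prediction scale
#'   (<= 0.01).
#' @param max_range_factor Plausibility bound: a side is abandoned (and
#'   flagged unbounded) once the scan is this many problem scales away from
#'   the optimum without having crossed the threshold.
#' @param init_step_fraction Initial step, as a fraction of the problem
#'   scale.
#' @param min_step_fraction,max_step_fraction Clamps for the adaptive step,
#'   as fractions of the problem scale.
#' @param refine If `TRUE` (default), each threshold crossing is localized
#'   by root-finding on the re-optimized profile and the crossing point is
#'   inserted into the grid, so that interval bounds are accurate well
#'   beyond the grid resolution.
#' @param refine_tol_fraction Abscissa tolerance of the crossing
#'   root-finding, as a fraction of the problem scale.
#' @param feasibility_pen_factor A penalized scan point whose penalty term
#'   alone exceeds this multiple of (threshold + margin) while the profile
#'   itself is still below the threshold is interpreted as lying beyond the
#'   feasibility boundary of the prediction (e.g. negative concentrations);
#'   the side ends there without an unbounded flag.
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(step_fraction = 0.2,
                        max_steps_per_side = 200L,
                        threshold_margin = 1.0,
                        constraint_sd_fraction = 1e-3,
                        max_range_factor = 10,
                        init_step_fraction = 0.05,
                        min_step_fraction = 1e-4,
                        max_step_fraction = 0.5,
                        refine = TRUE,
                        refine_tol_fraction = 1e-7,
                        feasibility_pen_factor = 4) {
  if (max_steps_per_side < 10L) stop_config("max_steps_per_side must be >= 10")
  if (threshold_margin < 0) stop_config("threshold_margin must be >= 0")
  if (constraint_sd_fraction <= 0 || constraint_sd_fraction > 0.01)
    stop_config("constraint_sd_fraction must be in (0, 0.01]")
  structure(list(step_fraction = step_fraction,
                 max_steps_per_side = as.integer(max_steps_per_side),
                 threshold_margin = threshold_margin,
                 constraint_sd_fraction = constraint_sd_fraction,
                 max_range_factor = max_range_factor,
                 init_step_fraction = init_step_fraction,
                 min_step_fraction = min_step_fraction,
                 max_step_fraction = max_step_fraction,
                 refine = refine,
                 refine_tol_fraction = refine_tol_fraction,
                 feasibility_pen_factor = feasibility_pen_factor),
            class = "scan_config")
}

# Generic one-dimensional profile scan.
#
# eval_fn(z, warm) must return a list with elements
#   ok       : logical, did the inner optimization succeed
#   value    : -2 log profile likelihood at this point (thresholding scale)
#   grid     : abscissa to report (defaults to z; differs for the
#              penalized-and-rescaled prediction profile)
#   pen      : penalty contribution on the -2LL scale (0 if none)
#   infeasible: optional logical (hard-constraint infeasibility)
#   warm     : warm start for the next point
#   extra    : optional named numeric vector, constant names across calls
#
# Returns list(points = data.frame, sides = list(left, right)).
scan_profile <- function(eval_fn, z0, f0, warm0, threshold, scan, scale,
                         lower = -Inf, upper = Inf,
                         pen_infeasibility = FALSE, extra0 = NULL) {
  level <- f0 + threshold
  stop_level <- level + scan$threshold_margin
  pen_cap <- scan$feasibility_pen_factor * (threshold + scan$threshold_margin)

  mk_row <- function(scan_z, grid, value, pen, extra) {
    row <- data.frame(scan_z = scan_z, grid = grid, value = value, pen = pen)
    if (!is.null(extra)) row <- cbind(row, as.data.frame(as.list(extra)))
    row
  }
  rows <- list(mk_row(z0, z0, f0, 0, extra0))

  run_side <- function(dir) {
    step <- scan$init_step_fraction * scale
    warm <- warm0
    zcur <- z0
    prev <- f0
    nfail <- 0L
    n <- 0L
    reason <- NULL
    side_rows <- list()
    last_below <- list(z = z0, warm = warm0, value = f0)  # last point at/below `level`
    last_r <- NULL
    while (is.null(reason)) {
      if (n >= scan$max_steps_per_side) { reason <- "max_steps"; break }
      n <- n + 1L
      znew <- zcur + dir * step
      hit_bound <- FALSE
      if (znew <= lower) { znew <- lower; hit_bound <- TRUE }
      if (znew >= upper) { znew <- upper; hit_bound <- TRUE }
      if ((dir > 0 && znew <= zcur) || (dir < 0 && znew >= zcur)) {
        reason <- "bound"; break
      }
      r <- eval_fn(znew, warm)
      if (!isTRUE(r$ok)) {
        nfail <- nfail + 1L
        if (nfail >= 3L) { reason <- "failed"; break }
        step <- max(step * 0.5, scan$min_step_fraction * scale)
        next
      }
      nfail <- 0L
      last_r <- r
      warm <- r$warm %||% warm
      side_rows[[length(side_rows) + 1L]] <-
        mk_row(znew, r$grid %||% znew, r$value, r$pen %||% 0, r$extra)
      dval <- r$value - prev
      prev <- r$value
      zcur <- znew
      # A constraint the optimizer cannot satisfy is a true feasibility
      # boundary when the attainable response saturates at zero (structural
      # positivity of concentrations) or when it pins without any free
      # parameter touching the box (pure model structure, e.g. an initial
      # condition fixed at zero).  Saturation elsewhere with parameters at
      # the box means the box, not the structure, is limiting: within the
      # declared parameter ranges the data do not exclude values beyond the
      # scan, so that side counts as unbounded (non-observable).
      structural <- abs(r$grid %||% znew) <= 0.01 * scale ||
        !isTRUE(r$at_bound)
      if (isTRUE(r$infeasible)) {
        reason <- if (structural) "infeasible" else "bound"; break
      }
      if (r$value > stop_level) { reason <- "crossed"; break }
      if (r$value <= level) last_below <- list(z = znew, warm = warm,
                                               value = r$value)
      if (pen_infeasibility && (r$pen %||% 0) > pen_cap) {
        reason <- if (structural) "infeasible" else "bound"; break
      }
      if (hit_bound) { reason <- "bound"; break }
      if (abs(znew - z0) > scan$max_range_factor * scale) { reason <- "range"; break }
      target <- scan$step_fraction * threshold
      fac <- if (dval <= 0) 2 else min(2, max(1 / 3, target / dval))
      step <- clamp(step * fac, scan$min_step_fraction * scale,
                    scan$max_step_fraction * scale)
    }
    crossed <- identical(reason, "crossed")

    # localize the crossing by root finding and insert it into the grid
    if (crossed && isTRUE(scan$refine) && zcur != last_below$z) {
      root_r <- NULL
      root_warm <- last_below$warm
      h <- function(z) {
        r <- eval_fn(z, root_warm)
        if (!isTRUE(r$ok)) return(NA_real_)
        root_warm <<- r$warm %||% root_warm
        root_r <<- r
        r$value - level
      }
      fr_out <- prev - level              # value at zcur (beyond level)
      fr_in <- last_below$value - level   # value at last point at/below level
      root <- tryCatch(
        stats::uniroot(h, lower = min(last_below$z, zcur),
                       upper = max(last_below$z, zcur),
                       f.lower = if (dir > 0) fr_in else fr_out,
                       f.upper = if (dir > 0) fr_out else fr_in,
                       tol = scan$refine_tol_fraction * scale),
        error = function(e) NULL)
      if (!is.null(root) && !is.null(root_r)) {
        side_rows[[length(side_rows) + 1L]] <-
          mk_row(root$root, root_r$grid %||% root$root, root_r$value,
                 root_r$pen %||% 0, root_r$extra)
      }
    }
    list(rows = side_rows,
         info = list(reason = reason %||% "none", crossed = crossed,
                     n_points = length(side_rows)))
  }

  right <- run_side(+1)
  left <- run_side(-1)
  pts <- do.call(rbind, c(rows, left$rows, right$rows))
  pts <- pts[order(pts$grid), , drop = FALSE]
  rownames(pts) <- NULL
  list(points = pts, sides = list(left = left$info, right = right$info))
}

#' Construct a profile-likelihood curve
#'
#' Container for a scanned profile: a strictly increasing grid of parameter
#' or prediction values with the corresponding -2 log profile likelihood.
#' Normally produced by [profile_parameter()], [ppl_scan()] or [vpl_scan()];
#' the constructor is exported so curves can also be assembled from external
#' results.
#'
#' @param grid Abscissa values (parameter value, or prediction value z).
#' @param neg2PL -2 log profile likelihood at each grid point (same
#'   arbitrary offset as `neg2LL_star`).
#' @param neg2LL_star -2 log-likelihood at the global fit optimum.
#' @param kind One of `"parameter"`, `"prediction"`, `"validation"`.
#' @param sides Optional list with entries `left`/`right`, each a list with
#'   `reason` (why the scan stopped) and `crossed` (did the profile exceed
#'   the threshold before the scan limit).
#' @param extra Optional data.frame of per-point bookkeeping (e.g. the
#'   fitted model response `zprime` recorded during a validation scan).
#' @param alpha Confidence level the scan was refined for (or `NA`).
#' @param scale Problem scale used by the scan (or `NA`).
#' @return An object of class `profile_curve`.
#' @export
profile_curve <- function(grid, neg2PL, neg2LL_star,
                          kind = c("parameter", "prediction", "validation"),
                          sides = NULL, extra = NULL, alpha = NA_real_,
                          scale = NA_real_) {
  kind <- match.arg(kind)
  stopifnot(length(grid) == length(neg2PL))
  o <- order(grid)
  grid <- grid[o]; neg2PL <- neg2PL[o]
  if (!is.null(extra)) extra <- extra[o, , drop = FALSE]
  span <- diff(range(grid))
  tol_g <- max(1e-12, 1e-9 * span)
  keep <- rep(TRUE, length(grid))
  if (length(grid) > 1) {
    last_kept <- 1L
    for (i in 2:length(grid)) {
      if (grid[i] - grid[last_kept] < tol_g) {
        # collapse near-duplicate abscissae, keeping the lower profile value
        if (neg2PL[i] < neg2PL[last_kept]) {
          keep[last_kept] <- FALSE
          last_kept <- i
        } else keep[i] <- FALSE
      } else last_kept <- i
    }
  }
  grid <- grid[keep]; neg2PL <- neg2PL[keep]
  if (!is.null(extra)) extra <- extra[keep, , drop = FALSE]
  tol_v <- 1e-4 * (1 + abs(neg2LL_star)) + 1e-6
  if (min(neg2PL) < neg2LL_star - tol_v)
    warning("profile dips below the reported optimum by ",
            format(neg2LL_star - min(neg2PL)),
            "; the global fit may not have converged", call. = FALSE)
  sides <- sides %||% list(left = list(reason = "none", crossed = FALSE),
                           right = list(reason = "none", crossed = FALSE))
  structure(list(grid = grid, neg2PL = neg2PL, neg2LL_star = neg2LL_star,
                 kind = kind, left_crossed = isTRUE(sides$left$crossed),
                 right_crossed = isTRUE(sides$right$crossed), sides = sides,
                 extra = extra, alpha = alpha, scale = scale,
                 degenerate = length(grid) < 3 ||
                   diff(range(grid)) < max(1e-12, 1e-8 * abs(mean(grid)))),
            class = "profile_curve")
}

#' @export
print.profile_curve <- function(x, ...) {
  cat("<profile_curve> kind=", x$kind, ", ", length(x$grid), " points on [",
      format(min(x$grid)), ", ", format(max(x$grid)), "], -2LL* = ",
      format(x$neg2LL_star), "\n", sep = "")
  cat("  stop reasons: left=", x$sides$left$reason, ", right=",
      x$sides$right$reason, "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.profile_curve <- function(x, ...) {
  df <- data.frame(grid = x$grid, neg2PL = x$neg2PL)
  if (!is.null(x$extra)) df <- cbind(df, x$extra)
  df
}

# reasons that signal an unbounded (non-observable / non-identifiable) side
# when the profile never crossed the threshold
unbounded_reasons <- c("max_steps", "range", "bound", "failed", "truncated",
                       "none")

#' Confidence interval by thresholding a profile curve
#'
#' The interval is the set of abscissa values whose -2 log profile
#' likelihood lies within `threshold` of the global optimum -2LL*
#' (likelihood-ratio construction).  Crossings are located by linear
#' interpolation between bracketing grid points (scans refine the crossing
#' into the grid beforehand, see [scan_config()]); with a non-monotone
#' profile the outermost crossings are taken, which is conservative.  A side
#' whose profile stayed below the threshold up to the scan limit is
#' returned with an unbounded flag -- the non-observability signal.  A side
#' that ended at a feasibility boundary (e.g. non-negative concentrations)
#' is bounded there without the flag.
#'
#' @param curve A [profile_curve()].
#' @param threshold Threshold on the -2 log-likelihood scale, see
#'   [profile_threshold()].
#' @param alpha Confidence level to record in the result (optional).
#' @return An object of class `profile_ci` with fields `lower`, `upper`
#'   (`-Inf`/`Inf` when unbounded), `unbounded_lower`, `unbounded_upper`,
#'   `estimate`, `alpha` and `threshold_used`.
#' @export
interval_from_curve <- function(curve, threshold, alpha = NA_real_) {
  stopifnot(inherits(curve, "profile_curve"), threshold >= 0)
  g <- curve$grid; v <- curve$neg2PL
  imin <- which.min(v)
  estimate <- g[imin]
  if (curve$degenerate) {
    return(structure(list(lower = estimate, upper = estimate,
                          unbounded_lower = FALSE, unbounded_upper = FALSE,
                          alpha = alpha, threshold_used = threshold,
                          estimate = estimate), class = "profile_ci"))
  }
  if (length(g) < 3) stop_config("profile curve needs at least 3 points")
  base <- curve$neg2LL_star
  level <- base + threshold
  tol <- 1e-9 * (1 + abs(level))
  below <- v <= level + tol
  if (!any(below))
    stop_config("profile curve minimum lies above the threshold; ",
                "the curve does not touch its own optimum")

  cross_at <- function(i, j) {
    # linear interpolation of the level crossing between grid points i < j
    if (v[j] == v[i]) return(g[j])
    g[i] + (level - v[i]) * (g[j] - g[i]) / (v[j] - v[i])
  }

  i_lo <- which(below)[1L]
  if (i_lo == 1L) {
    lower <- g[1L]
    unb_l <- !curve$left_crossed &&
      (curve$sides$left$reason %in% unbounded_reasons)
    if (unb_l) lower <- -Inf
  } else {
    lower <- cross_at(i_lo - 1L, i_lo)
    unb_l <- FALSE
  }
  i_hi <- rev(which(below))[1L]
  if (i_hi == length(g)) {
    upper <- g[length(g)]
    unb_r <- !curve$right_crossed &&
      (curve$sides$right$reason %in% unbounded_reasons)
    if (unb_r) upper <- Inf
  } else {
    upper <- cross_at(i_hi + 1L, i_hi)
    unb_r <- FALSE
  }
  structure(list(lower = lower, upper = upper,
                 unbounded_lower = unb_l, unbounded_upper = unb_r,
                 alpha = alpha, threshold_used = threshold,
                 estimate = estimate),
            class = "profile_ci")
}

#' @export
print.profile_ci <- function(x, ...) {
  lo <- if (x$unbounded_lower) "-Inf (unbounded)" else format(x$lower)
  hi <- if (x$unbounded_upper) "+Inf (unbounded)" else format(x$upper)
  cat("<profile_ci> [", lo, ", ", hi, "]",
      if (!is.na(x$alpha)) paste0(" at alpha = ", x$alpha),
      ", threshold = ", format(x$threshold_used), "\n", sep = "")
  invisible(x)
}
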