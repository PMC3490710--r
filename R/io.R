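#' Read / write a model declaration as YAML
#'
#' The YAML config mirrors the arguments of [ode_model()]: `name`,
#' `states`, `parameters` (name: value), `rhs`, `rates`, `observables`,
#' `initial_values`, `noise_sd`, `inputs`.  Expressions are plain strings.
#'
#' @param path File path.
#' @param model An [ode_model()].
#' @return `read_ode_model` returns the model; `write_ode_model` returns
#'   `path` invisibly.
#' @export
read_ode_model <- function(path) {
  y <- yaml::read_yaml(path)
  for (f in c("name", "states", "parameters", "rhs", "observables",
              "initial_values"))
    if (is.null(y[[f]])) stop_config("model config misses field '", f, "'")
  ode_model(
    name = y$name,
    states = unlist(y$states),
    parameters = unlist(y$parameters),
    rhs = y$rhs,
    observables = y$observables,
    initial_values = y$initial_values,
    noise_sd = if (!is.null(y$noise_sd)) unlist(y$noise_sd),
    rates = y$rates %||% list(),
    inputs = y$inputs %||% list()
  )
}

#' @rdname read_ode_model
#' @export
write_ode_model <- function(model, path) {
  stopifnot(inherits(model, "ode_model"))
  y <- list(name = model$name,
            states = model$states,
            parameters = as.list(model$parameters),
            rhs = model$rhs,
            observables = model$observables,
            initial_values = model$initial_values,
            noise_sd = if (!is.null(model$noise_sd)) as.list(model$noise_sd),
            rates = if (length(model$rates)) model$rates,
            inputs = if (length(model$input_vars)) model$inputs)
  yaml::write_yaml(y[!vapply(y, is.null, logical(1))], path)
  invisible(path)
}

#' Export a profile curve as CSV with a JSON sidecar
#'
#' Writes the scanned grid and -2 profile log-likelihood as
#' `grid,neg2PL` CSV; the confidence level, threshold, optimum and
#' boundary flags go to a JSON sidecar (same path with extension
#' `.json`).
#'
#' @param curve A [profile_curve()].
#' @param path CSV file path.
#' @param ci Optional `profile_ci` to include in the sidecar.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(curve, path, ci = NULL) {
  stopifnot(inherits(curve, "profile_curve"))
  utils::write.csv(data.frame(grid = curve$grid, neg2PL = curve$neg2PL),
                   path, row.names = FALSE, quote = FALSE)
  side <- list(kind = curve$kind, neg2LL_star = curve$neg2LL_star,
               alpha = curve$alpha,
               left_crossed = curve$left_crossed,
               right_crossed = curve$right_crossed,
               left_reason = curve$sides$left$reason,
               right_reason = curve$sides$right$reason)
  if (!is.null(ci)) side <- c(side, unclass(ci))
  jsonlite::write_json(side, sub("\\.[^.]+$", ".json", path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Export a confidence interval as JSON
#'
#' Writes `{lower, upper, alpha, threshold, unbounded_left,
#' unbounded_right}`; infinite bounds are written as `null` with the
#' corresponding unbounded flag set.
#'
#' @param ci A `profile_ci`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_interval_json <- function(ci, path) {
  stopifnot(inherits(ci, "profile_ci"))
  jsonlite::write_json(list(
    lower = if (is.finite(ci$lower)) ci$lower else NULL,
    upper = if (is.finite(ci$upper)) ci$upper else NULL,
    alpha = ci$alpha,
    threshold = ci$threshold_used,
    unbounded_left = ci$unbounded_lower,
    unbounded_right = ci$unbounded_upper
  ), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Export a confidence band as CSV
#'
#' Columns: `time,lower,upper,unbounded_l,unbounded_r`.
#'
#' @param band A [pci_band()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_band_csv <- function(band, path) {
  stopifnot(inherits(band, "confidence_band"))
  utils::write.csv(data.frame(time = band$time, lower = band$lower,
                              upper = band$upper,
                              unbounded_l = band$unbounded_lower,
                              unbounded_r = band$unbounded_upper),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
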