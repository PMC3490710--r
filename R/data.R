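#' Measurement-noise specification
#'
#' Gaussian observational noise with known standard deviation, the setting
#' under which minus two times the log-likelihood reduces to the weighted
#' residual sum of squares.
#'
#' @param sigma Positive standard deviation(s): a single number, a named
#'   vector per observable, or `NULL` to take the model's declared
#'   `noise_sd`.
#' @param seed Integer seed for the noise draw, or `NULL` to use the current
#'   RNG state.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sigma = NULL, seed = NULL) {
  if (!is.null(sigma) && any(sigma < 0)) stop_config("sigma must be >= 0")
  structure(list(distribution = "gaussian", sigma = sigma, seed = seed),
            class = "noise_spec")
}

resolve_sigma <- function(model, design, sigma) {
  obs <- design$observables
  if (is.null(sigma)) {
    sigma <- model$noise_sd
    if (is.null(sigma)) stop_config("no sigma given and model declares no noise_sd")
  }
  if (is.null(names(sigma))) {
    if (length(sigma) == 1L) sigma <- stats::setNames(rep(sigma, length(obs)), obs)
    else stop_config("sigma must be a single value or named per observable")
  }
  miss <- setdiff(obs, names(sigma))
  if (length(miss)) stop_config("no sigma for observable(s): ",
                                paste(miss, collapse = ", "))
  sigma[obs]
}

#' Simulate a noisy time-course dataset
#'
#' Generates measurements \eqn{y = g(x(t), \theta) + \epsilon} with i.i.d.
#' Gaussian noise under an experimental design.  With the same seed the
#' dataset is identical call for call.
#'
#' @param model An [ode_model()].
#' @param theta Parameter vector used as the data-generating truth.
#' @param design An [experimental_design()].
#' @param noise A [noise_spec()].
#' @return A `data.frame` with columns `time`, `observable`, `value`,
#'   `sigma`, carrying the design as attribute `"design"`.
#' @export
simulate_dataset <- function(model, theta, design, noise = noise_spec()) {
  stopifnot(inherits(design, "experimental_design"))
  sigma <- resolve_sigma(model, design, noise$sigma)
  traj <- integrate_model(model, theta, design$times, input = design$input)
  g <- observe(model, traj, theta, design$observables)
  draw <- function() {
    vals <- unlist(lapply(design$observables, function(o)
      g[, o] + stats::rnorm(length(design$times), 0, sigma[[o]])))
    data.frame(
      time = rep(design$times, times = length(design$observables)),
      observable = rep(design$observables, each = length(design$times)),
      value = vals,
      sigma = rep(sigma, each = length(design$times)),
      row.names = NULL
    )
  }
  dat <- if (is.null(noise$seed)) draw() else with_seed(noise$seed, draw())
  attr(dat, "design") <- design
  dat
}

validate_dataset <- function(model, data) {
  need <- c("time", "observable", "value", "sigma")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop_config("dataset misses column(s): ",
                                paste(miss, collapse = ", "))
  if (any(!is.finite(data$sigma)) || any(data$sigma <= 0))
    stop_config("all sigma must be positive")
  for (o in unique(data$observable)) target_expr(model, o)  # must resolve
  invisible(TRUE)
}

dataset_input <- function(data) {
  d <- attr(data, "design")
  if (!is.null(d)) d$input else attr(data, "input") %||% "default"
}

#' Read / write time-course data as CSV
#'
#' The CSV has the header `time,observable,value,sigma` (decimal point,
#' comma separator).
#'
#' @param path File path.
#' @param data Dataset `data.frame` as produced by [simulate_dataset()].
#' @return `read_dataset_csv` returns the dataset `data.frame`;
#'   `write_dataset_csv` returns `path` invisibly.
#' @export
read_dataset_csv <- function(path) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "observable", "value", "sigma")
  miss <- setdiff(need, names(dat))
  if (length(miss)) stop_config("data CSV misses column(s): ",
                                paste(miss, collapse = ", "))
  dat[need]
}

#' @rdname read_dataset_csv
#' @export
write_dataset_csv <- function(data, path) {
  utils::write.csv(data[c("time", "observable", "value", "sigma")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a trajectory as CSV
#'
#' Writes the header `time,<state1>,...,<stateN>`.
#'
#' @param traj A `state_trajectory`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
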