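#' Declare an ODE state-space model
#'
#' Builds a state-space model \eqn{\dot x = f(x, u, \theta)} with an
#' observation map \eqn{y = g(x, \theta) + \epsilon}.  Right-hand sides,
#' observables and initial values are given as expression strings over the
#' state names, parameter names, input names, optional auxiliary rate names
#' and time `t`; they are parsed once and compiled to fast derivative
#' functions.  All parameters are assumed positive (kinetic rates, initial
#' concentrations, Michaelis constants, ...); estimation works on the log
#' scale.
#'
#' @param name Model name (used in printing and file export).
#' @param states Character vector of state identifiers.
#' @param parameters Named numeric vector of parameters with their default
#'   (or true/guess) values; all must be strictly positive.
#' @param rhs Named character vector or list, one expression per state,
#'   giving \eqn{dx/dt}.
#' @param observables Named character vector or list of observation
#'   expressions \eqn{g(x,\theta)}.
#' @param initial_values Named list, one entry per state: a number, or an
#'   expression string over the parameters (e.g. `"theta3"` for an estimated
#'   initial concentration).
#' @param noise_sd Named numeric vector of known measurement standard
#'   deviations per observable (same units as the observable), or `NULL` if
#'   sigmas always accompany the data.
#' @param rates Optional named list of auxiliary expressions (e.g.
#'   Michaelis-Menten fluxes) evaluated in order before the right-hand
#'   sides; rhs expressions may refer to them by name.
#' @param inputs Optional named list of input conditions.  Each condition is
#'   a named list mapping input variables to either a constant or a
#'   `data.frame(time, value)` interpreted as a piecewise-constant (step)
#'   function.  A condition named `"default"` is always available (empty if
#'   not given).
#' @return An object of class `ode_model`.
#' @examples
#' m <- ode_model("decay", states = "A", parameters = c(k = 0.1, A0 = 1),
#'                rhs = c(A = "-k * A"), observables = c(obs_A = "A"),
#'                initial_values = list(A = "A0"), noise_sd = c(obs_A = 0.1))
#' traj <- integrate_model(m, c(k = 0.1, A0 = 1), times = 0:10)
#' @export
ode_model <- function(name, states, parameters, rhs, observables,
                      initial_values, noise_sd = NULL, rates = list(),
                      inputs = list()) {
  states <- as.character(states)
  if (!length(states)) stop_config("model needs at least one state")
  if (is.null(names(parameters)) || any(names(parameters) == ""))
    stop_config("'parameters' must be a fully named numeric vector")
  if (any(!is.finite(parameters)) || any(parameters <= 0))
    stop_config("all default parameter values must be positive and finite")
  rhs <- lapply(rhs, as.character)
  if (!setequal(names(rhs), states) || length(rhs) != length(states))
    stop_config("'rhs' must contain exactly one expression per state")
  rhs <- rhs[states]
  observables <- lapply(observables, as.character)
  if (!length(observables) || is.null(names(observables)))
    stop_config("'observables' must be a named list of expressions")
  if (!setequal(names(initial_values), states))
    stop_config("'initial_values' must contain exactly one entry per state")
  initial_values <- initial_values[states]

  input_vars <- unique(unlist(lapply(inputs, names)))
  if (!"default" %in% c(names(inputs), character(0)) && length(input_vars) == 0)
    inputs$default <- list()
  if (!"default" %in% names(inputs)) inputs$default <- inputs[[1L]]
  for (cn in names(inputs)) {
    miss <- setdiff(input_vars, names(inputs[[cn]]))
    if (length(miss))
      stop_config("input condition '", cn, "' misses input(s): ",
                  paste(miss, collapse = ", "))
  }

  pnames <- names(parameters)
  rate_names <- names(rates)
  allowed_dyn <- c(states, pnames, rate_names, input_vars, "t", "pi")

  rhs_exprs <- lapply(seq_along(rhs), function(i)
    parse_expr1(rhs[[i]], paste0("rhs of ", states[i])))
  seen_rates <- character(0)
  rate_exprs <- lapply(seq_along(rates), function(i) {
    ex <- parse_expr1(as.character(rates[[i]]), paste0("rate ", rate_names[i]))
    check_symbols(ex, c(states, pnames, seen_rates, input_vars, "t", "pi"),
                  paste0("rate ", rate_names[i]))
    seen_rates <<- c(seen_rates, rate_names[i])
    ex
  })
  for (i in seq_along(rhs_exprs))
    check_symbols(rhs_exprs[[i]], allowed_dyn, paste0("rhs of ", states[i]))
  obs_exprs <- lapply(seq_along(observables), function(i) {
    ex <- parse_expr1(observables[[i]], paste0("observable ", names(observables)[i]))
    # observation expressions are evaluated on stored trajectories, where
    # auxiliary rate values are not retained, hence no rate names here
    check_symbols(ex, c(states, pnames, input_vars, "t", "pi"),
                  paste0("observable ", names(observables)[i]))
    ex
  })
  names(obs_exprs) <- names(observables)
  init_exprs <- lapply(states, function(s) {
    iv <- initial_values[[s]]
    ex <- if (is.numeric(iv)) iv else parse_expr1(as.character(iv),
                                                  paste0("initial value of ", s))
    if (!is.numeric(ex))
      check_symbols(ex, c(pnames, "pi"), paste0("initial value of ", s))
    ex
  })
  names(init_exprs) <- states

  if (!is.null(noise_sd)) {
    bad <- setdiff(names(noise_sd), names(observables))
    if (length(bad)) stop_config("noise_sd given for unknown observable(s): ",
                                 paste(bad, collapse = ", "))
    if (any(noise_sd <= 0)) stop_config("noise_sd must be > 0")
  }

  m <- structure(list(
    name = name, states = states, parameters = parameters,
    rhs = lapply(rhs, identity), observables = lapply(observables, identity),
    initial_values = initial_values, noise_sd = noise_sd,
    rates = lapply(rates, as.character), inputs = inputs,
    input_vars = input_vars,
    .exprs = list(rhs = rhs_exprs, rates = rate_exprs, obs = obs_exprs,
                  init = init_exprs),
    .cache = new.env(parent = emptyenv())
  ), class = "ode_model")
  m
}

#' @export
print.ode_model <- function(x, ...) {
  cat("<ode_model> ", x$name, "\n", sep = "")
  cat("  states     : ", paste(x$states, collapse = ", "), "\n", sep = "")
  cat("  parameters : ", paste(sprintf("%s=%g", names(x$parameters), x$parameters),
                               collapse = ", "), "\n", sep = "")
  cat("  observables: ", paste(names(x$observables), collapse = ", "), "\n", sep = "")
  if (length(x$input_vars))
    cat("  inputs     : ", paste(x$input_vars, collapse = ", "),
        " (conditions: ", paste(names(x$inputs), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

resolve_theta <- function(model, theta) {
  pn <- names(model$parameters)
  if (is.null(names(theta))) {
    if (length(theta) != length(pn))
      stop_config("theta must have length ", length(pn))
    names(theta) <- pn
  } else {
    full <- model$parameters
    bad <- setdiff(names(theta), pn)
    if (length(bad)) stop_config("unknown parameter(s): ", paste(bad, collapse = ", "))
    full[names(theta)] <- theta
    theta <- full
  }
  theta
}

# Compile the derivative function for one input condition.  The generated
# function binds states and parameters by position, evaluates auxiliary
# rates in declaration order and returns the state derivatives.
compile_rhs <- function(model, input = "default") {
  key <- paste0("rhs::", input)
  if (!is.null(model$.cache[[key]])) return(model$.cache[[key]])
  cond <- model$inputs[[input]]
  if (is.null(cond)) stop_config("unknown input condition '", input, "'")

  bind <- c(
    sprintf("%s <- y[[%dL]]", model$states, seq_along(model$states)),
    sprintf("%s <- p[[%dL]]", names(model$parameters),
            seq_along(model$parameters))
  )
  fun_env <- new.env(parent = asNamespace("pplik"))
  for (iv in model$input_vars) {
    v <- cond[[iv]]
    if (is.data.frame(v)) {
      fn <- stats::approxfun(v$time, v$value, method = "constant", rule = 2)
      assign(paste0(".in_", iv), fn, envir = fun_env)
      bind <- c(bind, sprintf("%s <- .in_%s(t)", iv, iv))
    } else {
      bind <- c(bind, sprintf("%s <- %.17g", iv, as.numeric(v)))
    }
  }
  bind <- c(bind, sprintf("%s <- %s", names(model$rates),
                          vapply(model$rates, identity, character(1))))
  body_txt <- paste0(
    "function(t, y, p) {\n",
    paste(bind, collapse = "\n"), "\n",
    "list(c(", paste(vapply(model$rhs, identity, character(1)), collapse = ",\n"),
    "))\n}"
  )
  fn <- eval(parse(text = body_txt, keep.source = FALSE)[[1L]], envir = fun_env)
  model$.cache[[key]] <- fn
  fn
}

initial_state <- function(model, theta) {
  env <- as.list(theta)
  y0 <- vapply(model$.exprs$init, function(ex) {
    if (is.numeric(ex)) ex else eval(ex, env)
  }, numeric(1))
  names(y0) <- model$states
  y0
}

#' Integrate a model's ODE system
#'
#' Solves \eqn{\dot x = f(x, u, \theta)} from the initial condition at
#' \eqn{t = 0} with a stiff-capable solver (`deSolve::lsoda`).  Tight
#' tolerances are the default because profile optimization requires the
#' objective to be smooth well below the chi-square threshold scale.
#'
#' @param model An [ode_model()].
#' @param theta Parameter vector (named or in declaration order).
#' @param times Increasing, non-negative output times.
#' @param input Name of the input condition.
#' @param rtol,atol Relative and absolute solver tolerances.
#' @return A `state_trajectory`: list with `times` and a `states` matrix
#'   (one row per requested time, one column per state).  Integration
#'   failure raises a condition of class `pplik_integration_error` carrying
#'   the offending `theta` (never silent `NaN`s).
#' @export
integrate_model <- function(model, theta, times, input = "default",
                            rtol = 1e-8, atol = 1e-10) {
  theta <- resolve_theta(model, theta)
  times <- as.numeric(times)
  if (any(diff(times) <= 0)) stop_config("'times' must be strictly increasing")
  if (any(times < 0)) stop_config("'times' must be non-negative")
  tt <- if (times[1] > 0) c(0, times) else times
  y0 <- initial_state(model, theta)
  cm <- if (condition_is_constant(model, input)) compiled_model(model)
  out <- tryCatch(suppressWarnings({
    if (!is.null(cm)) {
      cond <- model$inputs[[input]]
      parms <- c(theta, vapply(model$input_vars,
                               function(iv) as.numeric(cond[[iv]]),
                               numeric(1)))
      deSolve::ode(y = y0, times = tt, func = "pplik_derivs", parms = parms,
                   dllname = cm$dll, initfunc = "pplik_initmod",
                   method = "lsoda", rtol = rtol, atol = atol)
    } else {
      deSolve::ode(y = y0, times = tt, func = compile_rhs(model, input),
                   parms = theta, method = "lsoda", rtol = rtol, atol = atol)
    }
  }), error = function(e) NULL)
  # a solver abort can return fewer rows than requested (deSolve truncates
  # at the failure time), so the returned time column must be verified too
  ok <- !is.null(out) && nrow(out) == length(tt) && all(is.finite(out)) &&
    max(abs(out[, 1L] - tt)) <= 1e-8 * (1 + max(tt))
  if (!ok)
    stop_integration(paste0("ODE integration failed for model '", model$name, "'"),
                     theta)
  sel <- if (times[1] > 0) -1L else seq_along(tt)
  states <- out[sel, -1L, drop = FALSE]
  rownames(states) <- NULL
  structure(list(times = times, states = states, input = input, theta = theta,
                 model = model$name),
            class = "state_trajectory")
}

#' @export
print.state_trajectory <- function(x, ...) {
  cat("<state_trajectory> model ", x$model, ", ", length(x$times),
      " time points, states: ", paste(colnames(x$states), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.state_trajectory <- function(x, ...) {
  data.frame(time = x$times, x$states, check.names = FALSE)
}

# Evaluate an arbitrary expression over states/parameters/time on a
# trajectory; returns a numeric vector along the trajectory times.
eval_on_trajectory <- function(model, traj, theta, expr, input = "default") {
  theta <- resolve_theta(model, theta)
  if (is.character(expr)) expr <- parse_expr1(expr, "prediction expression")
  check_symbols(expr, c(model$states, names(model$parameters),
                        model$input_vars, "t", "pi"),
                "prediction expression")
  env <- c(lapply(seq_along(model$states), function(j) traj$states[, j]),
           as.list(theta))
  names(env)[seq_along(model$states)] <- model$states
  env$t <- traj$times
  cond <- model$inputs[[input]]
  for (iv in model$input_vars) {
    v <- cond[[iv]]
    env[[iv]] <- if (is.data.frame(v))
      stats::approxfun(v$time, v$value, method = "constant", rule = 2)(traj$times)
    else as.numeric(v)
  }
  val <- eval(expr, env)
  rep_len(as.numeric(val), length(traj$times))
}

#' Evaluate noise-free observables along a trajectory
#'
#' Applies the observation map \eqn{g(x, \theta)} (without measurement
#' noise) to an integrated trajectory.
#'
#' @param model An [ode_model()].
#' @param traj A `state_trajectory` produced for the same model and `theta`.
#' @param theta Parameter vector used for the trajectory.
#' @param observables Character vector of observable names (default: all).
#' @return Matrix with one row per trajectory time and one column per
#'   observable.
#' @export
observe <- function(model, traj, theta, observables = NULL) {
  observables <- observables %||% names(model$observables)
  bad <- setdiff(observables, names(model$observables))
  if (length(bad)) stop_config("unknown observable(s): ", paste(bad, collapse = ", "))
  out <- vapply(observables, function(nm)
    eval_on_trajectory(model, traj, theta, model$.exprs$obs[[nm]], traj$input),
    numeric(length(traj$times)))
  out <- matrix(out, nrow = length(traj$times),
                dimnames = list(NULL, observables))
  out
}

#' Define a prediction condition
#'
#' A prediction condition consists of a quantity of interest (any expression
#' over states and parameters: a state, a sum or ratio of states, ...), a
#' prediction time and a stimulation condition.  It need not coincide with a
#' measured observable.
#'
#' @param observable Expression string, or the name of a declared observable.
#' @param time Non-negative prediction time.
#' @param input Input condition name.
#' @return An object of class `prediction_target`.
#' @export
prediction_target <- function(observable, time, input = "default") {
  if (!is_scalar_number(time) || time < 0)
    stop_config("'time' must be a single non-negative number")
  structure(list(observable = as.character(observable), time = as.numeric(time),
                 input = input),
            class = "prediction_target")
}

#' @export
print.prediction_target <- function(x, ...) {
  cat("<prediction_target> ", x$observable, " at t = ", x$time,
      " (input: ", x$input, ")\n", sep = "")
  invisible(x)
}

# Resolve a target observable to an expression (declared observable name or
# raw expression string).
target_expr <- function(model, observable) {
  if (observable %in% names(model$observables))
    model$.exprs$obs[[observable]]
  else {
    ex <- parse_expr1(observable, "prediction expression")
    check_symbols(ex, c(model$states, names(model$parameters),
                        model$input_vars, "t", "pi"), "prediction expression")
    ex
  }
}

#' Model response for a prediction condition
#'
#' Computes the model prediction \eqn{z = F(D_{pred}, \theta)}: the
#' prediction expression evaluated on the integrated trajectory at the
#' prediction time.
#'
#' @param object An [ode_model()].
#' @param theta Parameter vector.
#' @param target A [prediction_target()].
#' @param rtol,atol Solver tolerances, see [integrate_model()].
#' @param ... Unused.
#' @return The scalar prediction `z`.
#' @export
predict.ode_model <- function(object, theta, target, rtol = 1e-8,
                              atol = 1e-10, ...) {
  stopifnot(inherits(target, "prediction_target"))
  traj <- integrate_model(object, theta, times = target$time,
                          input = target$input, rtol = rtol, atol = atol)
  ex <- target_expr(object, target$observable)
  eval_on_trajectory(object, traj, theta, ex, target$input)[[1L]]
}

#' Define an experimental design
#'
#' The design \eqn{D = \{t, g, u\}} collects the controllable conditions of
#' an experiment: measurement times, measured observables and the input
#' (stimulation) condition.
#'
#' @param times Strictly increasing, non-negative measurement times.
#' @param observables Non-empty character vector of observable names.
#' @param input Input condition name.
#' @return An object of class `experimental_design`.
#' @export
experimental_design <- function(times, observables, input = "default") {
  times <- as.numeric(times)
  if (any(diff(times) <= 0) || any(times < 0))
    stop_config("design times must be strictly increasing and non-negative")
  if (!length(observables)) stop_config("design needs at least one observable")
  structure(list(times = times, observables = as.character(observables),
                 input = input),
            class = "experimental_design")
}

#' Define a validation experiment
#'
#' Couples a prediction condition with the measurement error `sd` of the
#' future validation data point \eqn{z \sim N(\mu, sd^2)} (same units as the
#' predicted quantity).
#'
#' @param target A [prediction_target()].
#' @param sd Positive measurement standard deviation of the validation
#'   measurement.
#' @return An object of class `validation_setup`.
#' @export
validation_setup <- function(target, sd) {
  stopifnot(inherits(target, "prediction_target"))
  if (!is_scalar_number(sd) || sd <= 0) stop_config("'sd' must be > 0")
  structure(list(target = target, sd = as.numeric(sd)),
            class = "validation_setup")
}
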