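`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global random-number-generator state set from `seed`
#' and restores the previous state afterwards, so library calls do not
#' perturb a user's random stream.
#'
#' @param seed Integer seed (< 2^31).
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# move a start strictly inside a box: nls.lm does not move a parameter
# that starts exactly on its bound
inward <- function(par, lb, ub, frac = 1e-7) {
  w <- frac * (ub - lb)
  pmin(pmax(par, lb + w), ub - w)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("pplik_config_error", "error")))
}

stop_integration <- function(msg, theta) {
  stop(errorCondition(msg, theta = theta,
                      class = c("pplik_integration_error", "error")))
}

# parse a single expression string, refusing multi-statement input
parse_expr1 <- function(text, what = "expression") {
  ex <- tryCatch(parse(text = text, keep.source = FALSE),
                 error = function(e) stop_config("cannot parse ", what, " '", text, "': ",
                                                conditionMessage(e)))
  if (length(ex) != 1L) stop_config(what, " must be a single expression: '", text, "'")
  ex[[1L]]
}

check_symbols <- function(expr, allowed, what) {
  bad <- setdiff(all.vars(expr), allowed)
  if (length(bad))
    stop_config("unknown symbol(s) in ", what, ": ",
                paste(bad, collapse = ", "))
  invisible(TRUE)
}
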