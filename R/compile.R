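# Compiled model back end.  The symbolic right-hand sides are translated to
# C, built once with R CMD SHLIB and used through deSolve's compiled-model
# interface; models whose inputs are time-varying, or environments without a
# working toolchain, fall back transparently to the interpreted R
# derivatives.  Shared objects are cached per R session, keyed by a checksum
# of the generated source, so re-creating a model re-uses the library.

.compile_registry <- new.env(parent = emptyenv())

# R expression -> C expression; `rename` maps symbols (e.g. t -> tt_)
expr_to_c <- function(e, rename = list()) {
  rec <- function(e) expr_to_c(e, rename)
  if (is.numeric(e) || is.integer(e)) return(sprintf("%.17g", as.numeric(e)))
  if (is.symbol(e)) {
    nm <- as.character(e)
    if (nm == "pi") return("M_PI")
    return(rename[[nm]] %||% nm)
  }
  if (is.call(e)) {
    op <- as.character(e[[1]])
    a <- as.list(e)[-1]
    return(switch(op,
      "+" = if (length(a) == 1L) sprintf("(+%s)", rec(a[[1]]))
            else sprintf("(%s + %s)", rec(a[[1]]), rec(a[[2]])),
      "-" = if (length(a) == 1L) sprintf("(-%s)", rec(a[[1]]))
            else sprintf("(%s - %s)", rec(a[[1]]), rec(a[[2]])),
      "*" = sprintf("(%s * %s)", rec(a[[1]]), rec(a[[2]])),
      "/" = sprintf("(%s / %s)", rec(a[[1]]), rec(a[[2]])),
      "^" = sprintf("pow(%s, %s)", rec(a[[1]]), rec(a[[2]])),
      "(" = sprintf("(%s)", rec(a[[1]])),
      "exp" = , "log" = , "sqrt" = , "sin" = , "cos" = , "tan" =
        sprintf("%s(%s)", op, rec(a[[1]])),
      "abs" = sprintf("fabs(%s)", rec(a[[1]])),
      stop_config("cannot translate function '", op, "' to C")
    ))
  }
  stop_config("cannot translate expression element of class ",
              class(e)[1], " to C")
}

model_c_source <- function(model) {
  pn <- names(model$parameters)
  npar <- length(pn) + length(model$input_vars)
  rename <- list(t = "tt_")
  decl_y <- sprintf("  double %s = y[%d];", model$states,
                    seq_along(model$states) - 1L)
  decl_p <- sprintf("  double %s = parms_[%d];",
                    c(pn, model$input_vars), seq_len(npar) - 1L)
  decl_r <- if (length(model$rates))
    sprintf("  double %s = %s;", names(model$rates),
            vapply(model$.exprs$rates, expr_to_c, character(1),
                   rename = rename))
  dy <- sprintf("  ydot[%d] = %s;", seq_along(model$states) - 1L,
                vapply(model$.exprs$rhs, expr_to_c, character(1),
                       rename = rename))
  paste(c(
    "#include <R.h>",
    "#include <math.h>",
    sprintf("static double parms_[%d];", npar),
    "void pplik_initmod(void (* odeparms)(int *, double *)) {",
    sprintf("  int N = %d;", npar),
    "  odeparms(&N, parms_);",
    "}",
    "void pplik_derivs(int *neq, double *t, double *y, double *ydot,",
    "                  double *yout, int *ip) {",
    "  double tt_ = *t; (void) tt_; (void) neq; (void) yout; (void) ip;",
    decl_y, decl_p, decl_r, dy,
    "}"), collapse = "\n")
}

# returns list(dll = basename) or NULL when compilation is unavailable
compiled_model <- function(model) {
  if (!isTRUE(getOption("pplik.compile", TRUE))) return(NULL)
  cache <- model$.cache
  if (!is.null(cache$compiled)) {
    return(if (identical(cache$compiled, "failed")) NULL else cache$compiled)
  }
  res <- tryCatch({
    src <- model_c_source(model)
    key <- paste0("pplik", substr(digest_string(src), 1, 16))
    hit <- .compile_registry[[key]]
    if (!is.null(hit)) {
      hit
    } else {
      dir <- file.path(tempdir(), key)
      dir.create(dir, showWarnings = FALSE)
      cfile <- file.path(dir, paste0(key, ".c"))
      writeLines(src, cfile)
      sofile <- file.path(dir, paste0(key, .Platform$dynlib.ext))
      owd <- setwd(dir)
      ok <- tryCatch(
        system2(file.path(R.home("bin"), "R"),
                c("CMD", "SHLIB", basename(cfile)),
                stdout = FALSE, stderr = FALSE) == 0L,
        finally = setwd(owd))
      if (!ok || !file.exists(sofile)) stop("SHLIB failed")
      dyn.load(sofile)
      out <- list(dll = key)
      .compile_registry[[key]] <- out
      out
    }
  }, error = function(e) NULL)
  cache$compiled <- res %||% "failed"
  res
}

# minimal string checksum (two polynomial hashes over the bytes); only a
# session cache key, not cryptographic
digest_string <- function(s) {
  b <- as.integer(charToRaw(s))
  h1 <- 0; h2 <- 0
  for (x in b) {
    h1 <- (h1 * 31 + x) %% 2147483647
    h2 <- (h2 * 131 + x) %% 2147483629
  }
  sprintf("%08x%08x", h1, h2)
}

# does this input condition allow the compiled path (constants only)?
condition_is_constant <- function(model, input) {
  cond <- model$inputs[[input]]
  !any(vapply(cond, is.data.frame, logical(1)))
}
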