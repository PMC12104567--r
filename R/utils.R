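# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so generators are pure functions of (config, seed).
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Classed stop() so callers/tests can distinguish validation, parameter,
# parse and I/O errors.
bsr_stop <- function(msg, class = "bsr_validation_error", ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "bsr_error", "error", "condition")))
}

stop_validation <- function(msg, ...) bsr_stop(msg, "bsr_validation_error", ...)
stop_parameter  <- function(msg, ...) bsr_stop(msg, "bsr_parameter_error", ...)
stop_parse      <- function(msg, ...) bsr_stop(msg, "bsr_parse_error", ...)
stop_io         <- function(msg, ...) bsr_stop(msg, "bsr_io_error", ...)
stop_config     <- function(msg, ...) bsr_stop(msg, "bsr_config_error", ...)

# Check a half-open [start, end) window: numeric, finite, ordered.
check_window <- function(window, what = "window") {
  if (!is.numeric(window) || length(window) != 2L || any(!is.finite(window))) {
    stop_parameter("%s must be a finite numeric vector c(start_s, end_s)", what)
  }
  if (window[2] <= window[1]) {
    stop_parameter("%s must satisfy start_s < end_s (got [%g, %g))",
                   what, window[1], window[2])
  }
  invisible(window)
}

rms <- function(x) sqrt(mean(x^2))

sem <- function(x) stats::sd(x) / sqrt(length(x))
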