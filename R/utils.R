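#' @keywords internal
"_PACKAGE"

# Classed conditions so callers (and the CLI) can map failure modes to exit
# codes without string-matching messages.
dili_abort <- function(class, message, call = sys.call(-1)) {
  cond <- structure(
    class = c(class, "dili_error", "error", "condition"),
    list(message = message, call = call)
  )
  stop(cond)
}

abort_invalid_argument  <- function(msg) dili_abort("dili_invalid_argument", msg)
abort_insufficient_data <- function(msg) dili_abort("dili_insufficient_data", msg)
abort_invalid_state     <- function(msg) dili_abort("dili_invalid_state", msg)
abort_format            <- function(msg) dili_abort("dili_format_error", msg)
abort_validation        <- function(msg) dili_abort("dili_validation_error", msg)
abort_undefined_metric  <- function(msg) dili_abort("dili_undefined_metric", msg)
abort_join              <- function(msg) dili_abort("dili_join_error", msg)

# Run code with a fixed RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort_invalid_argument("`seed` must be a single integer")
  }
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
  force(code)
}

#' Round a percentage half away from zero to one decimal
#'
#' Cohort fractions are reported in text outputs to one decimal place with
#' halves rounded away from zero, so 22/24 prints as 91.7 and 11/24 as 45.8
#' (base [round()] uses round-half-even and would disagree on some inputs).
#'
#' @param x Numeric vector of percentages.
#' @return Numeric vector rounded to one decimal.
#' @examples
#' round_percent1(100 * 22 / 24) # 91.7
#' @export
round_percent1 <- function(x) {
  sign(x) * floor(abs(x) * 10 + 0.5) / 10
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_invalid_argument(sprintf("`%s` must be a single finite number", name))
  }
}
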