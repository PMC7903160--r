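# Internal helpers: error signalling, seeded evaluation, seed splitting.

stop_unlearnr <- function(class, message, call. = FALSE) {
  cond <- structure(
    class = c(class, "unlearnr_error", "error", "condition"),
    list(message = message, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  )
  stop(cond)
}

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers do not disturb the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic seed splitting: all randomness in a run flows from one master
# seed; children are derived with a fixed integer hash kept below 2^31.
split_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647)
  as.integer((s * 48271 + 7919 * as.double(index)) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_finite <- function(x, what) {
  if (!all(is.finite(x)))
    stop_unlearnr("unlearnr_error_nonfinite",
                  sprintf("non-finite values in %s", what))
  invisible(x)
}
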