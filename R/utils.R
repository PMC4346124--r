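#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's
#' RNG state afterwards, so library functions never perturb the session
#' stream.
#'
#' @param seed integer scalar seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
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
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a named sub-stream seed from a base seed
#'
#' Splits one user-facing seed into independent per-purpose streams so that
#' adding samples (or stages) never perturbs earlier draws.  The derived
#' value stays inside the 32-bit signed integer range R requires.
#'
#' @param seed base integer seed.
#' @param ... integers and/or strings identifying the sub-stream.
#' @return An integer in `[0, 2^31 - 1)`.
#' @keywords internal
derive_seed <- function(seed, ...) {
  parts <- list(...)
  h <- as.double(seed) %% 2147483647
  for (p in parts) {
    if (is.character(p)) {
      p <- sum(utf8ToInt(p) * (seq_along(utf8ToInt(p)) %% 97 + 1))
    }
    # 48271 is a classic Lehmer multiplier; arithmetic stays in double range
    h <- (h * 48271 + as.double(p) + 1) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
  invisible(TRUE)
}
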