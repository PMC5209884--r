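`%||%` <- function(x, y) if (is.null(x)) y else x

bdx_stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "bdx_error")))
}

assert_scalar_number <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    bdx_stop("bdx_domain_error", "%s must be a single non-missing number", what)
  }
  invisible(as.numeric(x))
}

assert_probability <- function(x, what) {
  assert_scalar_number(x, what)
  if (x < 0 || x > 1) {
    bdx_stop("bdx_domain_error", "%s must lie in [0, 1], got %g", what, x)
  }
  invisible(as.numeric(x))
}

assert_count <- function(x, what, positive = FALSE) {
  assert_scalar_number(x, what)
  if (x < 0 || x != round(x)) {
    bdx_stop("bdx_domain_error", "%s must be a non-negative integer, got %g", what, x)
  }
  if (positive && x == 0) {
    bdx_stop("bdx_domain_error", "%s must be positive", what)
  }
  invisible(as.integer(x))
}

assert_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    bdx_stop("bdx_domain_error", "%s must be a single non-empty string", what)
  }
  invisible(x)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  assert_count(seed, "seed")
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
  set.seed(seed)
  code
}
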