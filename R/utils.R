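# Small shared helpers. Nothing here is exported.

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Round-half-up on the positive Likert range (base round() is banker's
# rounding; half-up is the documented discretization rule).
round_half_up <- function(x) floor(x + 0.5)

# Deterministic sub-seed derivation: every random draw in the package flows
# from one user seed through named substreams so that stages are reproducible
# independently of evaluation order. Kept below 2^31 - 1.
derive_seed <- function(seed, ...) {
  parts <- vapply(list(...), as.character, character(1))
  h <- as.double(seed %% 2147483647L)
  for (p in parts) {
    for (ch in utf8ToInt(p)) {
      h <- (h * 31 + ch) %% 2147483629
    }
  }
  as.integer(h %% 2147483646) + 1L
}

with_seed <- function(seed, code) {
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
  force(code)
}

stop_invalid <- function(msg, class) {
  rlang::abort(msg, class = c(class, "trustfuse_error"))
}

assert_scalar_in <- function(x, lo, hi, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    stop_invalid(
      sprintf("`%s` must be a single finite number in [%g, %g].", name, lo, hi),
      "trustfuse_invalid_argument"
    )
  }
  invisible(x)
}
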