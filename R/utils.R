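#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# Derive a sub-stream seed from a master seed and a stream counter, so that
# each module draws from an independent, reproducible stream. Arithmetic kept
# in doubles (< 2^53) and reduced mod 2^31 - 1 so the result is a valid R
# integer seed.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  s <- abs(as.numeric(seed)) %% 2147483647
  as.integer((s * 69069 + 104729 * as.numeric(stream)) %% 2147483647)
}

# Evaluate `expr` under a given seed without clobbering the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

check_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < min || x > max) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, min, max, x))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
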