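#' @keywords internal
"_PACKAGE"

# Deterministic 32-bit stream seed from a root seed and a string key.
# Used so that per-pathway / per-network RNG streams do not depend on
# iteration order.
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  m <- 2147483647
  h <- as.double(seed) %% m
  for (ch in utf8ToInt(as.character(key))) {
    h <- (h * 31 + ch) %% m
  }
  as.integer(h)
}

# Evaluate expr with a locally set RNG seed; the caller's RNG state is
# restored afterwards. seed = NULL leaves the global stream untouched.
with_rng_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
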