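#' Derive a reproducible sub-seed from a master seed and a label
#'
#' The simulator splits one master seed into independent per-module seeds
#' (field layout, detection noise, trajectory jitter, sampling) so that
#' changing, say, the noise settings does not reshuffle the field layout.
#'
#' @param seed integer master seed.
#' @param label character tag naming the consumer (e.g. "field", "noise").
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(seed) + 1000003 * h) %% 2147483646)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; restores
# the caller's RNG afterwards so library code never clobbers user state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(..., call. = FALSE)
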