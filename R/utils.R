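#' @keywords internal
"_PACKAGE"

# Deterministic per-stage seed derivation: every source of randomness in the
# package draws from a stream named after its stage, so stages can be
# regenerated independently from one top-level seed. Kept below 2^31.
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}

# run `expr` under a local RNG state seeded from (seed, stream); restores the
# caller's .Random.seed afterwards
with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
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
  set.seed(stream_seed(seed, stream))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# population standard deviation (divisor n, not n-1)
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

abort_xdrg <- function(msg, class) {
  stop(structure(
    class = c(class, "xdrg_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
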