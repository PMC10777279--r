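#' Deterministic 31-bit string hash
#'
#' Polynomial rolling hash over the UTF-8 bytes of its arguments, reduced
#' modulo a Mersenne-adjacent prime. Used to derive independent RNG streams
#' per (seed, rater, image) so simulated demarcations do not depend on the
#' order in which they are generated.
#'
#' @param ... atomic values, concatenated with a separator before hashing.
#' @return a single integer in `[0, 2^31 - 46)`.
#' @keywords internal
hash_stream <- function(...) {
  s <- paste(vapply(list(...), as.character, character(1)), collapse = "\r")
  bytes <- utf8ToInt(s)
  h <- 0
  p <- 2147483629 # largest prime below 2^31 minus a little headroom
  for (b in bytes) h <- (h * 131 + b) %% p
  h
}

# Evaluate `code` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cm <- function(...) stop(..., call. = FALSE)
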