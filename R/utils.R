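# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed, runs `code`, and restores the previous RNG state so
#' library code never clobbers the caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
local_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Deterministically derive a substream seed (< 2^31) from a base seed and a
# sequence of integer keys. Linear congruential mixing keeps everything in
# exact double arithmetic (48271 * m < 2^53).
derive_seed <- function(seed, ...) {
  keys <- c(...)
  m <- 2147483647
  s <- as.double(seed) %% m
  for (k in keys) {
    s <- (s * 48271 + (as.double(k) + 1) * 9973 + 17) %% m
  }
  as.integer(s)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
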