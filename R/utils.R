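# Numerically safe logistic; drives in this model stay small so the plain
# form is adequate, but guard the tails anyway.
sigmoid <- function(x) {
  out <- 1 / (1 + exp(-x))
  # keep strictly inside (0,1) so downstream entropy estimates stay finite
  pmin(pmax(out, .Machine$double.eps), 1 - .Machine$double.eps)
}

#' Derive a substream seed from a master seed and a stream label
#'
#' All randomness in the package flows from one master seed through named
#' substreams (scenes, gaze, permutations, noise-train, noise-test, ...),
#' so that independent stages draw from decorrelated, reproducible streams.
#'
#' @param master integer master seed.
#' @param stream character label of the substream.
#' @return An integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @export
#' @examples
#' substream_seed(1, "gaze")
substream_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(stream))
  m <- 2147483647  # 2^31 - 1, Mersenne prime modulus
  h <- 0
  for (b in utf8ToInt(stream)) h <- (h * 131 + b) %% m
  as.integer(((abs(master) %% m) * 48271 + h) %% m)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

rescale01 <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(array(0, dim = dim(x)))
  (x - r[1]) / (r[2] - r[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)
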