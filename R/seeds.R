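# Named random-number substreams.
#
# All randomness in the package flows from one top-level seed through named
# substreams, so pipeline stages are individually reproducible and do not
# perturb each other or the caller's RNG state.

stream_hash <- function(stream) {
  if (!nchar(stream)) return(0)
  v <- utf8ToInt(stream)
  h <- 0
  for (x in v) h <- (h * 131 + x) %% 2147483647
  h
}

#' Create a named RNG substream
#'
#' @param seed integer master seed.
#' @param stream substream name (e.g. a pipeline stage).
#' @return An RNG handle for [with_rng()].
#' @export
make_rng <- function(seed, stream = "") {
  seed <- as.numeric(seed)
  if (is.na(seed)) stop("seed is mandatory", call. = FALSE)
  sub <- (abs(seed) %% 2147483647 + 1000003 * stream_hash(stream)) %% 2147483647
  e <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(as.integer(sub))
  e$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  else rm(".Random.seed", envir = globalenv())
  e
}

#' Evaluate an expression under an RNG substream
#'
#' Swaps the substream's state in, evaluates, saves the advanced state back,
#' and restores the caller's RNG state.
#'
#' @param rng handle from [make_rng()].
#' @param expr expression using R's RNG.
#' @return Value of `expr`.
#' @export
with_rng <- function(rng, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}
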