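#' Named random-number substreams
#'
#' The simulator draws randomness for three distinct purposes: object
#' sampling (`"sampling"`), activity noise (`"noise"`) and weight
#' initialization (`"init"`).  Each purpose gets its own Mersenne-Twister
#' stream derived from the master seed, so changing how one consumer draws
#' (e.g. adding a noise source) does not perturb the others.
#'
#' @param seed master integer seed.
#' @return an environment of class `"ag_rng"` holding one saved
#'   `.Random.seed` per stream.
#' @export
ag_rng <- function(seed) {
  rng <- new.env(parent = emptyenv())
  rng$master <- as.integer(seed)
  streams <- c("sampling", "noise", "init")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  for (i in seq_along(streams)) {
    # derived seeds kept well inside 32-bit integer range
    set.seed((as.integer(seed) %% 599999L) * 3001L + 7L * i)
    rng[[streams[i]]] <- get(".Random.seed", globalenv())
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  class(rng) <- "ag_rng"
  rng
}

#' Evaluate an expression under a named substream
#'
#' Swaps the stream's state into the global RNG, evaluates `expr`, and saves
#' the advanced state back, restoring whatever global state was present.
#'
#' @param rng an [ag_rng()] object.
#' @param stream one of `"sampling"`, `"noise"`, `"init"`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_stream <- function(rng, stream, expr) {
  stopifnot(inherits(rng, "ag_rng"))
  if (is.null(rng[[stream]])) stop("unknown RNG stream: ", stream, call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", rng[[stream]], globalenv())
  on.exit({
    rng[[stream]] <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, globalenv())
    }
  })
  expr
}
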