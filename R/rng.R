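#' Deterministic named random streams
#'
#' Every stochastic component of the package draws its seed from a single
#' global seed through a named-stream splitter, so adding a stage to a
#' pipeline never perturbs the draws of earlier stages.
#'
#' @param seed Integer global seed.
#' @param name Character stream name (e.g. `"simulate"`, `"cube_benign_003"`).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @examples
#' stream_seed(1, "simulate")
#' stream_seed(1, "train")
#' @export
stream_seed <- function(seed, name) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_config("seed must be a single finite number")
  m <- 2147483647 # 2^31 - 1, prime
  h <- 5381
  for (ch in utf8ToInt(as.character(name)))
    h <- (h * 33 + ch) %% m
  s <- ((abs(as.numeric(seed)) %% m) * 48271 + h) %% m
  as.integer(max(1, s))
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards.  `seed = NULL` runs in the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
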