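#' Round half away from zero
#'
#' Percentages reported by the pipeline use conventional "half-up" rounding
#' (0.05 -> 0.1), not the IEEE banker's rounding of [base::round()].
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Derive a reproducible sub-seed from a root seed and a stream name
#'
#' All randomness in the package flows from one root seed through named
#' substreams, so that changing one table's recipe does not perturb the
#' draws of another.
#'
#' @param seed integer root seed.
#' @param name character stream label.
#' @return an integer in [0, 2^31 - 2] usable with [set.seed()].
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  h <- abs(as.double(seed)) %% 2147483647
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Evaluate expr under a named substream, restoring the caller's RNG state.
with_substream <- function(seed, name, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  force(expr)
}

abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Avogadro constant (1/mol), exact SI value.
AVOGADRO <- 6.02214076e23

VALID_CHROMOSOMES <- c(as.character(1:22), "X", "Y", "MT")
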