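#' @importFrom methods new validObject is slot setValidity show
#' @importFrom stats fft median rnorm runif setNames
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors metadata DataFrame
NULL

## Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## Derive a reproducible substream seed (< 2^31) from a master seed and a set
## of integer indices (subject, arm, cycle, movement, ...). Multiplicative
## hash mod a Mersenne prime; any single substream is reproducible in
## isolation without generating the ones before it.
deriveSeed <- function(master, ...) {
  idx <- c(...)
  h <- as.double(master %% 2147483647L)
  for (v in idx) {
    h <- (h * 31 + as.double(v) + 7) %% 2147483647
  }
  as.integer(h)
}

## Moving-RMS envelope with a centred window of `width` samples (odd).
movingRms <- function(x, width) {
  width <- as.integer(width)
  if (width %% 2L == 0L) width <- width + 1L
  k <- rep(1 / width, width)
  sq <- stats::filter(x^2, k, sides = 2)
  sq[is.na(sq)] <- 0
  sqrt(pmax(as.numeric(sq), 0))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

isCount <- function(x) length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
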