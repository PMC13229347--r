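## Internal numerical helpers shared across the model and losses.

sigmoid <- function(x) 1 / (1 + exp(-x))

## Numerically safe softplus: log(1 + exp(x)) without overflow for large x.
softplus <- function(x) {
  out <- pmax(x, 0) + log1p(exp(-abs(x)))
  out
}

## Exact (erf-based) GELU and its derivative.
gelu <- function(x) x * stats::pnorm(x)

geluGrad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

## Row-wise softmax of a matrix, stable under large scores.
rowSoftmax <- function(z) {
  m <- apply(z, 1L, max)
  e <- exp(z - m)
  e / rowSums(e)
}

#' @keywords internal
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assertCount <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != floor(x)) {
    stopf("'%s' must be a single integer >= %d", name, min)
  }
  as.integer(x)
}

assertFraction <- function(x, name, lo = 0, hi = 1, openLo = TRUE, openHi = TRUE) {
  ok <- length(x) == 1L && is.numeric(x) && !is.na(x) &&
    (if (openLo) x > lo else x >= lo) && (if (openHi) x < hi else x <= hi)
  if (!ok) {
    stopf("'%s' must be a single number in %s%g, %g%s", name,
          if (openLo) "(" else "[", lo, hi, if (openHi) ")" else "]")
  }
  as.numeric(x)
}

## Seed offsets so each synthetic artifact (store / oracle / pairs) can be
## regenerated independently from a single user-facing seed.
deriveSeed <- function(seed, what = c("store", "oracle", "pairs", "train")) {
  what <- match.arg(what)
  offset <- c(store = 101L, oracle = 202L, pairs = 303L, train = 404L)[[what]]
  as.integer((as.integer(seed) + offset) %% .Machine$integer.max)
}

## Half-up rounding (round() in R rounds half to even).
roundHalfUp <- function(x) floor(x + 0.5)

## md5 digest of a serialized numeric matrix (provenance for fitted scalers).
matrixDigest <- function(X) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(serialize(unname(as.matrix(X)), NULL, version = 2L), tmp)
  unname(tools::md5sum(tmp))
}
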