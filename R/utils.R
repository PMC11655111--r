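#' @importFrom stats sd median quantile rnorm runif rpois rlnorm approx
#'   ecdf cov cor var fft filter mahalanobis hclust as.dist cutree
#'   predict aggregate qnorm
#' @importFrom methods new validObject is slot show
#' @importFrom utils head tail
NULL

## Deterministic sub-seed derivation: one root seed is expanded into
## independent named streams so that, e.g., adding a channel to the
## generator never perturbs the noise of another channel.  Plain
## polynomial string hash folded into the positive 31-bit range.
substreamSeed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- 0
  for (k in utf8ToInt(tag)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) * 2654435 + h * 97 + 12345) %% 2147483647)
}

## Evaluate `expr` under a local RNG state seeded with `seed`; the
## caller's RNG state is untouched. `seed = NULL` uses the current stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Sample skewness m3 / m2^(3/2); 0 for (near-)constant input.
sampleSkewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= .Machine$double.eps * max(1, m^2)) return(0)
  mean((x - m)^3) / m2^1.5
}

## Trapezoidal integral of y over grid x (uniform or not).
trapezInt <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}
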