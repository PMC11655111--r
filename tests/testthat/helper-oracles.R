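# Independent brute-force oracles used by the oracle-equivalence suites.
# These deliberately share no code with the package implementations.

# ApEn by its plain definition: explicit loops over template pairs,
# self-matches included, Chebyshev distance.
oracleApEn <- function(x, m, r) {
  n <- length(x)
  phi <- function(mm) {
    nm <- n - mm + 1L
    csum <- 0
    for (i in seq_len(nm)) {
      cnt <- 0L
      for (j in seq_len(nm)) {
        d <- 0
        for (k in 0:(mm - 1L)) d <- max(d, abs(x[i + k] - x[j + k]))
        if (d <= r) cnt <- cnt + 1L
      }
      csum <- csum + log(cnt / nm)
    }
    csum / nm
  }
  phi(m) - phi(m + 1L)
}

# Delta index by direct window enumeration.
oracleDeltaIndex <- function(x, fs, window_s = 12) {
  w <- window_s * fs
  means <- c()
  s <- 1
  while (s <= length(x)) {
    means <- c(means, mean(x[s:min(length(x), s + w - 1)]))
    s <- s + w
  }
  if (length(means) < 2) return(0)
  mean(abs(diff(means)))
}

# One analysis level of the periodized Daubechies-4 transform by direct
# double-loop circular correlation and decimation (odd lengths extended
# by repeating the last sample, as documented).
oracleDwtLevel <- function(x, lo, hi) {
  if (length(x) %% 2 == 1) x <- c(x, x[length(x)])
  n <- length(x)
  a <- d <- numeric(n / 2)
  for (i in seq_len(n / 2)) {
    sa <- sdd <- 0
    for (k in 0:7) {
      xi <- x[((2 * (i - 1) + k) %% n) + 1]
      sa <- sa + lo[k + 1] * xi
      sdd <- sdd + hi[k + 1] * xi
    }
    a[i] <- sa; d[i] <- sdd
  }
  list(a = a, d = d)
}

oracleDwt <- function(x, levels, lo, hi) {
  out <- list()
  a <- x
  for (l in seq_len(levels)) {
    st <- oracleDwtLevel(a, lo, hi)
    out[[paste0("d", l)]] <- st$d
    a <- st$a
  }
  out
}
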