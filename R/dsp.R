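## Shared signal-processing primitives used by the generator and the
## feature bank: Welch periodogram, prominence-based peak picking, a
## periodized Daubechies-4 DWT, and the acquisition-chain emulation
## (zero-phase band-limiting + 16-bit midtread quantization).

#' Welch power spectral density
#'
#' One-sided PSD estimate by Welch's method: Hann-windowed segments of
#' \code{nper} samples with 50\% overlap, periodograms averaged, density
#' scaling such that \code{sum(psd) * df} estimates the signal variance
#' (Parseval).
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param nper segment length in samples (default 4 s at \code{fs}).
#' @return list with \code{freq} (Hz) and \code{psd} (signal-units^2/Hz).
#' @keywords internal
welchPSD <- function(x, fs, nper = 4L * fs) {
  n <- length(x)
  nper <- min(as.integer(nper), n)
  step <- max(1L, nper %/% 2L)
  w <- 0.5 * (1 - cos(2 * pi * (0:(nper - 1L)) / nper))  # periodic Hann
  starts <- seq(1L, n - nper + 1L, by = step)
  nhalf <- nper %/% 2L
  acc <- numeric(nhalf + 1L)
  scale <- 1 / (fs * sum(w^2))
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)] * w
    X <- fft(seg)
    p <- (Mod(X[1:(nhalf + 1L)])^2) * scale
    p[2:nhalf] <- 2 * p[2:nhalf]             # fold negative frequencies
    acc <- acc + p
  }
  list(freq = (0:nhalf) * fs / nper, psd = acc / length(starts))
}

## Local maxima with topographic prominence >= minProm and a minimum
## horizontal separation; plateaus contribute their first sample.
## Returns integer indices sorted by position.
findPeaksProm <- function(x, minProm, minDistSamples = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- sign(diff(x))
  # carry the last non-zero slope through plateaus (vectorized LOCF)
  nz <- which(d != 0)
  if (!length(nz)) return(integer(0))
  pos <- findInterval(seq_along(d), nz)
  d <- d[nz][pmax(pos, 1L)]
  cand <- which(diff(d) < 0) + 1L
  cand <- cand[cand > 1L & cand < n]
  if (!length(cand)) return(integer(0))
  prom <- .peakProminences(as.numeric(x), as.integer(cand))
  keep <- cand[prom >= minProm]
  if (length(keep) < 2L || minDistSamples <= 1L) return(keep)
  # greedy suppression, tallest first
  ord <- keep[order(x[keep], decreasing = TRUE)]
  sel <- integer(0)
  for (i in ord)
    if (!length(sel) || all(abs(sel - i) >= minDistSamples)) sel <- c(sel, i)
  sort(sel)
}

## Daubechies-4 scaling (low-pass) decomposition filter, 8 taps.
.db4lo <- c(0.23037781330885523, 0.71484657055254150, 0.63088076792959040,
            -0.02798376941698385, -0.18703481171888114, 0.03084138183598697,
            0.03288301166698295, -0.01059740178499728)
.db4hi <- rev(.db4lo) * rep(c(1, -1), 4L)   # quadrature mirror

## One periodized analysis step: circular correlation with the filter,
## then dyadic decimation. Odd-length inputs are extended by repeating
## the last sample. FFT-based; the test suite holds an independent
## direct-summation oracle.
.dwtStep <- function(x) {
  if (length(x) %% 2L == 1L) x <- c(x, x[length(x)])
  n <- length(x)
  fl <- c(.db4lo, numeric(n - 8L))
  fh <- c(.db4hi, numeric(n - 8L))
  X <- fft(x)
  lo <- Re(fft(X * Conj(fft(fl)), inverse = TRUE)) / n
  hi <- Re(fft(X * Conj(fft(fh)), inverse = TRUE)) / n
  idx <- seq(1L, n, by = 2L)
  list(a = lo[idx], d = hi[idx])
}

#' Periodized multilevel discrete wavelet transform (Daubechies-4)
#'
#' @param x numeric vector (length >= 16 recommended).
#' @param levels number of decomposition levels.
#' @return list of detail coefficient vectors \code{d1..d<levels>} plus the
#'   final approximation \code{a<levels>}.
#' @keywords internal
dwtDb4 <- function(x, levels = 5L) {
  out <- list()
  a <- x
  for (l in seq_len(levels)) {
    st <- .dwtStep(a)
    out[[paste0("d", l)]] <- st$d
    a <- st$a
  }
  out[[paste0("a", levels)]] <- a
  out
}

## Acquisition-chain emulation: zero-phase Butterworth band limiting
## (low-pass order 4 at 30 Hz; optional high-pass order 2 at 0.05 Hz)
## followed by 16-bit midtread quantization over the channel's physical
## range. The zero-phase response is applied in the frequency domain as
## the squared analytic Butterworth magnitude (exactly what a
## forward-backward recursive pass realises), with mirror padding to
## suppress wrap-around; this is numerically exact at the ~1e-3
## normalized high-pass corner where cascaded recursion is fragile.
bandLimit <- function(x, fs = 100, highpass = TRUE) {
  n <- length(x)
  pad <- min(n, 40L * fs)
  xe <- c(rev(x[seq_len(pad)]), x, rev(x[(n - pad + 1L):n]))
  M <- stats::nextn(length(xe), c(2, 3, 5))
  xe <- c(xe, numeric(M - length(xe)))
  f <- abs(c(0:(M %/% 2), -((M - M %/% 2 - 1L):1)) * fs / M)
  G <- 1 / (1 + (f / 30)^8)                       # |H_lp, order 4|^2
  if (highpass) G <- G * f^4 / (f^4 + 0.05^4)     # |H_hp, order 2|^2
  y <- Re(fft(fft(xe) * G, inverse = TRUE)) / M
  y[(pad + 1L):(pad + n)]
}

## Gaussian noise with amplitude spectrum shape(f), via FFT shaping on a
## composite-length grid; unit SD. Used for the 1/f EOG background and
## the intrinsically band-limited audio source noise.
shapedNoise <- function(n, fs, shape) {
  M <- stats::nextn(n, c(2, 3, 5))
  f <- abs(c(0:(M %/% 2), -((M - M %/% 2 - 1L):1)) * fs / M)
  x <- Re(fft(fft(rnorm(M)) * shape(f), inverse = TRUE)) / M
  x <- x[seq_len(n)]
  x / sd(x)
}

## sample indices covering time window [a, b] seconds (1-based, clipped)
idxWindow <- function(a, b, n, fs = 100) {
  i0 <- max(1L, floor(a * fs) + 1L)
  i1 <- min(n, floor(b * fs) + 1L)
  if (i0 > i1) integer(0) else i0:i1
}

quantize16 <- function(x, lo, hi) {
  q <- (hi - lo) / (2^16 - 1)
  x <- pmin(pmax(x, lo), hi)
  round((x - lo) / q) * q + lo
}
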