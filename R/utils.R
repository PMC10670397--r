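#' @useDynLib neosleep, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx fft median quantile rnorm rpois runif rbinom sd
#'   var IQR dist setNames cor predict
#' @importFrom utils head read.csv tail write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram with a Hann window, 50% segment overlap and
#' per-segment mean removal. The one-sided density is scaled so that
#' \code{sum(psd) * df} approximates the signal variance.
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz.
#' @param nperseg segment length in samples (capped at \code{length(x)}).
#' @param noverlap overlap between segments in samples.
#' @return list with \code{freq} (Hz) and \code{psd} (power per Hz).
#' @export
welch_psd <- function(x, fs, nperseg = min(256L, length(x)),
                      noverlap = nperseg %/% 2L) {
  n <- length(x)
  stopifnot(n >= 8, fs > 0)
  nperseg <- min(as.integer(nperseg), n)
  noverlap <- min(as.integer(noverlap), nperseg - 1L)
  step <- nperseg - noverlap
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))  # Hann
  u <- sum(w^2)
  nfreq <- nperseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(fft(seg)[seq_len(nfreq)])^2
    acc <- acc + sp
  }
  psd <- acc / (length(starts) * fs * u)
  # one-sided: double everything except DC (and Nyquist when nperseg even)
  dbl <- rep(2, nfreq)
  dbl[1] <- 1
  if (nperseg %% 2L == 0L) dbl[nfreq] <- 1
  list(freq = (seq_len(nfreq) - 1) * fs / nperseg, psd = psd * dbl)
}

#' Spectral power within a frequency band
#'
#' Trapezoidal integration of a PSD over \code{[lo, hi]}, with linear
#' interpolation of the density at the band edges.
#'
#' @param spec list with \code{freq} and \code{psd} (as from [welch_psd()]).
#' @param lo,hi band edges in Hz.
#' @return nonnegative power.
#' @export
band_power <- function(spec, lo, hi) {
  f <- spec$freq; p <- spec$psd
  lo <- max(lo, min(f)); hi <- min(hi, max(f))
  if (hi <= lo) return(0)
  inside <- f > lo & f < hi
  fb <- c(lo, f[inside], hi)
  pb <- c(approx(f, p, xout = lo)$y, p[inside], approx(f, p, xout = hi)$y)
  max(trapz(fb, pb), 0)
}
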