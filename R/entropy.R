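#' Sample entropy
#'
#' SampEn(m, r) = -ln(A/B) where B counts length-m template matches and A
#' counts length-(m+1) matches over ordered pairs (Chebyshev distance strictly
#' below r, self-matches excluded). Returns \code{NA} when no matches exist at
#' either length.
#'
#' @param x numeric series with \code{length(x) > m + 1}.
#' @param m template length (default 2).
#' @param r tolerance, in the units of \code{x} (> 0). Callers conventionally
#'   use \code{0.2 * sd(x)}.
#' @return nonnegative entropy, or \code{NA}.
#' @export
sample_entropy <- function(x, m = 2, r) {
  if (m < 1 || r <= 0) stop("need m >= 1 and r > 0")
  x <- as.numeric(x)
  if (length(x) <= m + 1) return(NA_real_)
  ab <- .sampen_counts(x, as.integer(m), r)
  if (ab[1] == 0 || ab[2] == 0) return(NA_real_)
  -log(ab[1] / ab[2])
}

#' Approximate entropy
#'
#' Pincus ApEn(m, r) = phi(m) - phi(m+1), with self-matches included and
#' tolerance criterion \code{<= r}.
#'
#' @inheritParams sample_entropy
#' @export
approx_entropy <- function(x, m = 1, r) {
  if (m < 1 || r <= 0) stop("need m >= 1 and r > 0")
  x <- as.numeric(x)
  if (length(x) <= m + 1) return(NA_real_)
  .apen_phi(x, as.integer(m), r) - .apen_phi(x, as.integer(m) + 1L, r)
}

#' Sample entropy area under the curve
#'
#' Trapezoidal integral of SampEn(r) over a grid of tolerances (absolute
#' units). At small tolerances short series often have template matches at
#' length m but none at length m + 1; there the integrand uses the maximum
#' resolvable value \code{-log(2 / ((N - m - 1) * (N - m)))} (the entropy
#' implied by a single matched pair among all ordered pairs) instead of going
#' missing. The AUC is missing only when some grid point has no length-m
#' matches at all.
#'
#' @param x numeric series.
#' @param m template length.
#' @param r_grid increasing tolerance grid with at least 3 points; default
#'   \code{c(0.10, 0.15, 0.20, 0.25, 0.30) * sd(x)}.
#' @export
sampen_auc <- function(x, m = 2, r_grid = c(0.10, 0.15, 0.20, 0.25, 0.30) * sd(x)) {
  if (length(r_grid) < 3 || any(diff(r_grid) <= 0))
    stop("r_grid must be increasing with >= 3 points")
  x <- as.numeric(x)
  n <- length(x)
  if (n <= m + 1) return(NA_real_)
  cap <- -log(2 / ((n - m - 1) * (n - m)))
  se <- vapply(r_grid, function(r) {
    ab <- .sampen_counts(x, as.integer(m), r)
    if (ab[2] == 0) return(NA_real_)
    if (ab[1] == 0) return(cap)
    -log(ab[1] / ab[2])
  }, 0.0)
  if (anyNA(se)) return(NA_real_)
  trapz(r_grid, se)
}

#' Quadratic sample entropy
#'
#' QSE(m, r) = SampEn(m, r) + ln(2r); corrects SampEn for the tolerance width
#' so values are comparable across r.
#'
#' @inheritParams sample_entropy
#' @export
quadratic_sampen <- function(x, m = 2, r) {
  se <- sample_entropy(x, m, r)
  if (is.na(se)) return(NA_real_)
  se + log(2 * r)
}

#' Lempel-Ziv (LZ76) complexity
#'
#' The series is binarized at its median (values above the median map to 1)
#' and parsed into its exhaustive production history; the complexity is the
#' phrase count, by default normalized by \code{n / log2(n)} so that values
#' are comparable across lengths.
#'
#' @param x numeric series of length >= 2, or a logical/0-1 integer vector
#'   taken as already binarized.
#' @param normalize divide the phrase count by \code{n / log2(n)}.
#' @return complexity value.
#' @export
lempel_ziv <- function(x, normalize = TRUE) {
  n <- length(x)
  if (n < 2) stop("series too short")
  b <- if (is.logical(x) || (is.integer(x) && all(x %in% c(0L, 1L))))
    as.integer(x)
  else as.integer(x > median(x))
  cc <- .lz76_phrases(b)
  if (normalize) cc * log2(n) / n else as.numeric(cc)
}
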