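# Actigraphy feature family: per-frame motion values (from video block
# differencing or directly from the simulator) summarized by 8 epoch
# features.

motion_feature_names <- c("motion_mean", "motion_sd", "motion_sum",
                          "motion_count", "motion_p25", "motion_p50",
                          "motion_p75", "motion_p95")

#' Motion values from grayscale video frames
#'
#' Thresholded block differencing: for each frame, the motion value is the
#' number of 16x16 blocks whose mean absolute intensity difference from the
#' previous frame exceeds a threshold. The first frame scores 0.
#'
#' @param frames list of equally sized numeric grayscale matrices at the
#'   motion sampling rate.
#' @param block block edge length in pixels.
#' @param threshold_frac threshold as a fraction of the dynamic range.
#' @param dynamic_range intensity dynamic range of the frames (e.g. 255 for
#'   8-bit video).
#' @return nonnegative integer motion value per frame.
#' @export
motion_from_frames <- function(frames, block = 16, threshold_frac = 0.02,
                               dynamic_range = 255) {
  if (!length(frames)) return(numeric(0))
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent frame sizes")
  nbr <- dims[1, 1] %/% block
  nbc <- dims[2, 1] %/% block
  thr <- threshold_frac * dynamic_range
  out <- numeric(length(frames))
  for (f in seq_along(frames)[-1]) {
    d <- abs(frames[[f]] - frames[[f - 1]])
    cnt <- 0L
    for (i in seq_len(nbr)) {
      ri <- ((i - 1) * block + 1):(i * block)
      for (j in seq_len(nbc)) {
        cj <- ((j - 1) * block + 1):(j * block)
        if (mean(d[ri, cj]) > thr) cnt <- cnt + 1L
      }
    }
    out[f] <- cnt
  }
  out
}

#' Epoch-level motion features
#'
#' Mean, SD and sum of the motion values in the epoch; the count of nonzero
#' values smoothed across epochs by an exponentially weighted moving average
#' (\code{smoothed = alpha * raw + (1 - alpha) * previous}); and the
#' linear-interpolation percentiles P25/P50/P75/P95.
#'
#' @param values epoch motion series (e.g. 240 samples for 30 s at 8 Hz).
#' @param expected_len required series length; \code{NULL} skips the check.
#' @param prev_count previous epoch's smoothed count (\code{NULL} for the
#'   first epoch, which uses the raw count).
#' @param alpha EWMA weight on the current epoch.
#' @return named numeric vector of length 8.
#' @export
motion_epoch_features <- function(values, expected_len = NULL,
                                  prev_count = NULL, alpha = 0.3) {
  if (!is.null(expected_len) && length(values) != expected_len)
    stop("motion epoch has wrong length")
  raw <- sum(values > 0)
  smoothed <- if (is.null(prev_count)) raw
              else alpha * raw + (1 - alpha) * prev_count
  q <- quantile(values, c(0.25, 0.5, 0.75, 0.95), names = FALSE, type = 7)
  c(motion_mean = mean(values), motion_sd = sd(values),
    motion_sum = sum(values), motion_count = smoothed,
    motion_p25 = q[1], motion_p50 = q[2], motion_p75 = q[3],
    motion_p95 = q[4])
}

#' Extract the 8 motion features for one epoch
#'
#' @param epoch an epoch from [epochize()].
#' @param prev_count carry-over smoothed activity count from the previous
#'   epoch in the recording (the EWMA runs across epochs).
#' @param config a [feature_config()].
#' @return named numeric vector of length 8.
#' @export
extract_motion <- function(epoch, prev_count = NULL,
                           config = feature_config()) {
  motion_epoch_features(epoch$motion, expected_len = NULL,
                        prev_count = prev_count, alpha = config$ewma_alpha)
}
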