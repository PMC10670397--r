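# Cardiac feature family: 34 per-epoch features from the R-peak train and,
# when available, the raw ECG waveform.

cardiac_feature_names <- c(
  "beats_per_epoch", "rr_mean", "rr_median", "rr_sdnn", "rr_cv", "rr_min",
  "rr_max", "rr_range", "rr_iqr", "rmssd", "sdsd", "pnn20", "pnn50",
  "hr_mean", "hr_sd",
  "hrv_vlf", "hrv_lf", "hrv_hf", "hrv_shf", "hrv_uhf", "hrv_total_power",
  "hrv_lf_hf_ratio", "hrv_lf_norm", "hrv_hf_norm",
  "ecg_line_length", "ecg_line_length_mean", "ecg_line_length_sd",
  "decel_pct", "decel_mag",
  "rr_sampen", "rr_sampen_auc", "rr_qse",
  "ecg_lz", "rr_lz")

#' RR-interval series from R-peak times
#'
#' Successive differences in ms; intervals outside the physiological range
#' are flagged and excluded from HRV statistics (but keep their place in the
#' series).
#'
#' @param r_times R-peak times within the epoch, seconds.
#' @param range physiological RR range in ms, default 200-750.
#' @return list with \code{rr} (ms), logical \code{valid}, and \code{t}
#'   (time of each interval's closing beat, s).
#' @export
rr_from_rpeaks <- function(r_times, range = c(200, 750)) {
  if (length(r_times) < 2)
    return(list(rr = numeric(0), valid = logical(0), t = numeric(0)))
  rr <- diff(r_times) * 1000
  list(rr = rr, valid = rr >= range[1] & rr <= range[2], t = r_times[-1])
}

#' HRV band powers from an RR series
#'
#' The (valid) RR tachogram is linearly interpolated to a uniform grid,
#' mean-detrended, and a Welch spectrum is integrated over the configured
#' band edges.
#'
#' @param rrs result of [rr_from_rpeaks()].
#' @param bands named list of band edges in Hz.
#' @param interp_hz resampling rate.
#' @return named vector of band powers (ms^2), one per band; all \code{NA}
#'   when fewer than 8 valid intervals exist.
#' @export
hrv_band_powers <- function(rrs, bands = feature_config()$hrv_bands,
                            interp_hz = 4) {
  out <- setNames(rep(NA_real_, length(bands)), names(bands))
  rr <- rrs$rr[rrs$valid]; tt <- rrs$t[rrs$valid]
  if (length(rr) < 8) return(out)
  grid <- seq(tt[1], tt[length(tt)], by = 1 / interp_hz)
  if (length(grid) < 16) return(out)
  x <- approx(tt, rr, xout = grid)$y
  spec <- welch_psd(x - mean(x), fs = interp_hz,
                    nperseg = min(256L, length(x)))
  for (b in names(bands)) out[b] <- band_power(spec, bands[[b]][1], bands[[b]][2])
  out
}

#' ECG line-length features
#'
#' Total first-difference absolute sum over the epoch, plus the mean and SD
#' of the same quantity over 1-s sub-windows.
#'
#' @param ecg epoch ECG samples.
#' @param fs sampling rate, Hz.
#' @return numeric \code{c(line_length, mean, sd)}.
#' @export
line_length_features <- function(ecg, fs) {
  ll <- sum(abs(diff(ecg)))
  nw <- floor(length(ecg) / fs)
  if (nw < 1) return(c(ll, NA, NA))
  sub <- vapply(seq_len(nw), function(i)
    sum(abs(diff(ecg[((i - 1) * fs + 1):(i * fs)]))), 0.0)
  c(ll, mean(sub), if (nw > 1) sd(sub) else 0)
}

#' Heart-rate deceleration features
#'
#' A deceleration is a maximal run of at least \code{min_run} beats whose RR
#' exceeds a running-median baseline by the fraction \code{theta}.
#' \code{decel_pct} is the fraction of beats inside decelerations;
#' \code{decel_mag} is the mean over decelerations of the maximum fractional
#' RR excess (0 when no deceleration occurs).
#'
#' @param rrs result of [rr_from_rpeaks()].
#' @param theta fractional threshold (default 0.1).
#' @param window running-median window, beats.
#' @param min_run minimum run length, beats.
#' @return numeric \code{c(decel_pct, decel_mag)}; \code{NA}s with fewer than
#'   5 valid intervals.
#' @export
hr_decelerations <- function(rrs, theta = 0.1, window = 15, min_run = 2) {
  rr <- rrs$rr[rrs$valid]
  n <- length(rr)
  if (n < 5) return(c(NA_real_, NA_real_))
  k <- min(window, if (n %% 2 == 0) n - 1 else n)
  if (k %% 2 == 0) k <- k - 1
  baseline <- as.numeric(stats::runmed(rr, k, endrule = "median"))
  high <- rr >= (1 + theta) * baseline
  r <- rle(high)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= min_run)
  if (!length(runs)) return(c(0, 0))
  inside <- sum(r$lengths[runs])
  mags <- vapply(runs, function(k2) {
    idx <- starts[k2]:ends[k2]
    max(rr[idx] / baseline[idx] - 1)
  }, 0.0)
  c(inside / n, mean(mags))
}

#' Extract the 34 cardiac features for one epoch
#'
#' Frequency-domain band powers (VLF/LF/HF plus the extended sHF and uHF
#' bands), beat count, ECG line-length statistics, deceleration features,
#' sample-entropy measures (SampEn, its area under the tolerance curve, and
#' quadratic SampEn) of the RR series, Lempel-Ziv complexity of the ECG and
#' the RR series, and standard time-domain HRV statistics. Missing values
#' (too few beats, no ECG waveform) are propagated as \code{NA}, never
#' imputed here.
#'
#' @param epoch an epoch from [epochize()].
#' @param config a [feature_config()].
#' @return named numeric vector of length 34 in registry order.
#' @export
extract_cardiac <- function(epoch, config = feature_config()) {
  v <- setNames(rep(NA_real_, length(cardiac_feature_names)),
                cardiac_feature_names)
  v["beats_per_epoch"] <- length(epoch$rpeaks)
  rrs <- rr_from_rpeaks(epoch$rpeaks, config$rr_range)
  rr <- rrs$rr[rrs$valid]
  if (length(rr) >= 2) {
    v["rr_mean"] <- mean(rr); v["rr_median"] <- median(rr)
    v["rr_sdnn"] <- sd(rr); v["rr_cv"] <- sd(rr) / mean(rr)
    v["rr_min"] <- min(rr); v["rr_max"] <- max(rr)
    v["rr_range"] <- diff(range(rr)); v["rr_iqr"] <- IQR(rr)
    hr <- 60000 / rr
    v["hr_mean"] <- mean(hr); v["hr_sd"] <- sd(hr)
    d <- diff(rr)
    if (length(d) >= 2) {
      v["rmssd"] <- sqrt(mean(d^2)); v["sdsd"] <- sd(d)
      v["pnn20"] <- mean(abs(d) > 20); v["pnn50"] <- mean(abs(d) > 50)
    }
    v["rr_lz"] <- if (length(rr) >= 8) lempel_ziv(rr) else NA_real_
  }
  bp <- hrv_band_powers(rrs, config$hrv_bands, config$hrv_interp_hz)
  v["hrv_vlf"] <- bp["vlf"]; v["hrv_lf"] <- bp["lf"]; v["hrv_hf"] <- bp["hf"]
  v["hrv_shf"] <- bp["shf"]; v["hrv_uhf"] <- bp["uhf"]
  if (!anyNA(bp)) {
    v["hrv_total_power"] <- sum(bp)
    if (bp["hf"] > 0) v["hrv_lf_hf_ratio"] <- bp["lf"] / bp["hf"]
    lh <- bp["lf"] + bp["hf"]
    if (lh > 0) {
      v["hrv_lf_norm"] <- bp["lf"] / lh
      v["hrv_hf_norm"] <- bp["hf"] / lh
    }
  }
  if (!is.null(epoch$ecg)) {
    llf <- line_length_features(epoch$ecg, epoch$fs_ecg)
    v["ecg_line_length"] <- llf[1]
    v["ecg_line_length_mean"] <- llf[2]
    v["ecg_line_length_sd"] <- llf[3]
    dec <- max(1L, round(epoch$fs_ecg / config$lz_ecg_hz))
    xz <- epoch$ecg[seq(1, length(epoch$ecg), by = dec)]
    v["ecg_lz"] <- if (length(xz) >= 8 && sd(xz) > 0) lempel_ziv(xz)
                   else NA_real_
  }
  dc <- hr_decelerations(rrs, config$decel_theta, config$decel_window,
                         config$decel_min_run)
  v["decel_pct"] <- dc[1]; v["decel_mag"] <- dc[2]
  if (length(rr) > config$sampen_m + 1) {
    s <- sd(rr)
    if (s == 0) {
      v["rr_sampen"] <- 0; v["rr_sampen_auc"] <- 0
    } else {
      v["rr_sampen"] <- sample_entropy(rr, config$sampen_m,
                                       config$sampen_r_frac * s)
      v["rr_sampen_auc"] <- sampen_auc(rr, config$sampen_m,
                                       config$sampen_auc_grid * s)
      v["rr_qse"] <- quadratic_sampen(rr, config$sampen_m,
                                      config$sampen_r_frac * s)
    }
  }
  v
}
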