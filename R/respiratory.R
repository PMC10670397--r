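# Respiratory feature family: 41 per-epoch features from the effort signal.

resp_feature_names <- c(
  "bf_var", "bf_median", "bf_sd", "log_bpm", "bf_rel_change",
  "bb_corr_mean", "bb_corr_sd", "bb_corr_min", "bb_corr_max",
  "resp_log_vlf", "resp_log_lf", "resp_log_hf",
  "resp_norm_vlf", "resp_norm_lf", "resp_norm_hf",
  "resp_vlf_hf_ratio", "resp_lf_hf_ratio", "resp_total_power",
  "resp_dom_freq", "resp_log_dom_power",
  "std_median_peak", "std_median_trough", "apen_peaks", "apen_troughs",
  "median_peak_trough_diff", "log_pt_ratio_median", "log_pt_ratio_sd",
  "vol_cycle_median", "vol_inhale_median", "vol_exhale_median",
  "flow_cycle_median", "flow_inhale_median", "flow_exhale_median",
  "ie_time_ratio", "ie_flow_ratio",
  "amp_ratio_mean", "amp_ratio_sd", "amp_ratio_delta",
  "resp_sampen", "ie_time_ratio_breath", "ie_flow_ratio_breath")

# local extrema of x as sample indices; plateaus inherit the preceding slope
local_extrema <- function(x) {
  s <- sign(diff(x))
  notz <- s != 0
  if (sum(notz) < 2) return(list(peaks = integer(0), troughs = integer(0)))
  pos <- cumsum(notz)
  pos[pos == 0] <- 1L          # leading plateau takes the first real slope
  filled <- s[notz][pos]
  chg <- which(diff(filled) != 0) + 1L
  list(peaks = chg[filled[chg] < 0], troughs = chg[filled[chg] > 0])
}

# enforce peak/trough alternation, keeping the more extreme of consecutive
# same-type extrema
alternate_extrema <- function(idx, type, y) {
  if (!length(idx)) return(list(idx = integer(0), type = character(0)))
  o <- order(idx)
  idx <- idx[o]; type <- type[o]
  keep_idx <- idx[1]; keep_type <- type[1]
  for (k in seq_along(idx)[-1]) {
    last <- length(keep_idx)
    if (type[k] == keep_type[last]) {
      better <- if (type[k] == "peak") y[idx[k]] > y[keep_idx[last]]
                else y[idx[k]] < y[keep_idx[last]]
      if (better) keep_idx[last] <- idx[k]
    } else {
      keep_idx <- c(keep_idx, idx[k])
      keep_type <- c(keep_type, type[k])
    }
  }
  list(idx = keep_idx, type = keep_type)
}

#' Segment a respiratory epoch into breaths
#'
#' Alternating peak/trough detection with small-oscillation pruning: adjacent
#' extremum pairs whose amplitude falls below the prominence threshold are
#' removed iteratively, and alternation is re-enforced by keeping the larger
#' of consecutive same-type extrema.
#'
#' @param x respiratory effort samples for one epoch.
#' @param fs sampling rate, Hz.
#' @param min_prominence minimum peak-trough amplitude; default
#'   \code{0.2 * sd(x)}.
#' @param min_period minimum breath period in seconds (breaths shorter than
#'   this are dropped from the breath table).
#' @return list with \code{peaks} and \code{troughs} data frames
#'   (\code{time}, \code{amp}) and a per-breath table \code{breaths}
#'   (\code{t0, tp, t1, period, ti, te, amp_in, amp_ex}); empty segmentation
#'   when no breaths are found.
#' @export
segment_breaths <- function(x, fs, min_prominence = 0.2 * sd(x),
                            min_period = 0.5) {
  empty <- list(peaks = data.frame(time = numeric(0), amp = numeric(0)),
                troughs = data.frame(time = numeric(0), amp = numeric(0)),
                breaths = data.frame(t0 = numeric(0), tp = numeric(0),
                                     t1 = numeric(0), period = numeric(0),
                                     ti = numeric(0), te = numeric(0),
                                     amp_in = numeric(0), amp_ex = numeric(0)))
  if (length(x) < 2 * fs || sd(x) == 0) return(empty)
  ex <- local_extrema(x)
  alt <- alternate_extrema(c(ex$peaks, ex$troughs),
                           rep(c("peak", "trough"),
                               c(length(ex$peaks), length(ex$troughs))), x)
  idx <- alt$idx; type <- alt$type
  # prune smallest adjacent oscillations below the prominence threshold
  while (length(idx) >= 2) {
    amps <- abs(diff(x[idx]))
    j <- which.min(amps)
    if (amps[j] >= min_prominence) break
    sel <- setdiff(seq_along(idx), c(j, j + 1L))
    alt <- alternate_extrema(idx[sel], type[sel], x)
    idx <- alt$idx; type <- alt$type
  }
  if (length(idx) < 2) return(empty)
  tt <- (idx - 1) / fs
  pk <- type == "peak"
  peaks <- data.frame(time = tt[pk], amp = x[idx[pk]])
  troughs <- data.frame(time = tt[!pk], amp = x[idx[!pk]])
  # breaths: trough -> peak -> trough triples
  pos <- which(pk)
  pos <- pos[pos > 1 & pos < length(idx)]
  if (!length(pos)) return(list(peaks = peaks, troughs = troughs,
                                breaths = empty$breaths))
  breaths <- data.frame(
    t0 = tt[pos - 1], tp = tt[pos], t1 = tt[pos + 1],
    period = tt[pos + 1] - tt[pos - 1],
    ti = tt[pos] - tt[pos - 1], te = tt[pos + 1] - tt[pos],
    amp_in = x[idx[pos]] - x[idx[pos - 1]],
    amp_ex = x[idx[pos]] - x[idx[pos + 1]])
  breaths <- breaths[breaths$period >= min_period, , drop = FALSE]
  list(peaks = peaks, troughs = troughs, breaths = breaths)
}

#' Breath-rate statistics
#'
#' Instantaneous frequency per breath (1/period): variance, median and SD,
#' the log of breaths per minute, and the mean absolute frequency change per
#' second between successive breaths.
#'
#' @param seg a [segment_breaths()] result with at least 3 breaths.
#' @return named numeric of length 5 (NA-filled when under 3 breaths).
#' @export
rate_features <- function(seg) {
  out <- c(bf_var = NA_real_, bf_median = NA_real_, bf_sd = NA_real_,
           log_bpm = NA_real_, bf_rel_change = NA_real_)
  b <- seg$breaths
  if (nrow(b) < 3) return(out)
  f <- 1 / b$period
  out["bf_var"] <- var(f)
  out["bf_median"] <- median(f)
  out["bf_sd"] <- sd(f)
  out["log_bpm"] <- log(60 / mean(b$period))
  dt <- diff(b$tp)
  out["bf_rel_change"] <- mean(abs(diff(f)) / dt)
  out
}

#' Breath-by-breath correlation
#'
#' Each consecutive breath pair is resampled to a common length and Pearson
#' correlated; returns mean, SD, min and max over pairs. Zero-variance
#' breaths are skipped.
#'
#' @param x epoch samples.
#' @param fs sampling rate.
#' @param seg a [segment_breaths()] result.
#' @param n_resample common resampled breath length.
#' @return named numeric of length 4.
#' @export
breath_correlation <- function(x, fs, seg, n_resample = 40) {
  out <- c(bb_corr_mean = NA_real_, bb_corr_sd = NA_real_,
           bb_corr_min = NA_real_, bb_corr_max = NA_real_)
  b <- seg$breaths
  if (nrow(b) < 3) return(out)
  tt <- (seq_along(x) - 1) / fs
  shape <- function(i) {
    grid <- seq(b$t0[i], b$t1[i], length.out = n_resample)
    approx(tt, x, xout = grid)$y
  }
  cors <- numeric(0)
  prev <- shape(1)
  for (i in seq_len(nrow(b))[-1]) {
    cur <- shape(i)
    if (sd(prev) > 0 && sd(cur) > 0)
      cors <- c(cors, stats::cor(prev, cur))
    prev <- cur
  }
  if (!length(cors)) return(out)
  c(bb_corr_mean = mean(cors),
    bb_corr_sd = if (length(cors) > 1) sd(cors) else 0,
    bb_corr_min = min(cors), bb_corr_max = max(cors))
}

#' Respiratory spectral features
#'
#' Welch spectrum of the effort signal: log and normalized band powers in
#' VLF/LF/HF, the VLF/HF and LF/HF ratios, the total power over the analyzed
#' partition, the dominant (argmax) frequency and its log power. Normalized
#' powers divide by the total over the union of the three bands, so they sum
#' to ~1.
#'
#' @param x epoch samples.
#' @param fs sampling rate.
#' @param bands named list with vlf/lf/hf edges in Hz.
#' @return named numeric of length 11.
#' @export
resp_spectral_features <- function(x, fs,
                                   bands = feature_config()$resp_bands) {
  eps <- 1e-12
  spec <- welch_psd(x - mean(x), fs, nperseg = min(256L, length(x)))
  p <- vapply(bands, function(b) band_power(spec, b[1], b[2]), 0.0)
  total <- band_power(spec, min(vapply(bands, min, 0)),
                      max(vapply(bands, max, 0)))
  nz <- spec$freq > 0
  dom_i <- which.max(spec$psd[nz])
  c(resp_log_vlf = log(p[["vlf"]] + eps),
    resp_log_lf = log(p[["lf"]] + eps),
    resp_log_hf = log(p[["hf"]] + eps),
    resp_norm_vlf = if (total > 0) p[["vlf"]] / total else NA_real_,
    resp_norm_lf = if (total > 0) p[["lf"]] / total else NA_real_,
    resp_norm_hf = if (total > 0) p[["hf"]] / total else NA_real_,
    resp_vlf_hf_ratio = if (p[["hf"]] > 0) p[["vlf"]] / p[["hf"]] else NA_real_,
    resp_lf_hf_ratio = if (p[["hf"]] > 0) p[["lf"]] / p[["hf"]] else NA_real_,
    resp_total_power = total,
    resp_dom_freq = spec$freq[nz][dom_i],
    resp_log_dom_power = log(spec$psd[nz][dom_i] + eps))
}

#' Respiratory amplitude features
#'
#' Standardized medians of peak and trough amplitudes, approximate entropy of
#' the peak and trough amplitude sequences, the median per-breath
#' peak-to-trough difference, and the median and SD of the log peak/|trough|
#' ratio.
#'
#' @param seg a [segment_breaths()] result.
#' @param epoch_sd SD of the epoch signal used for standardization.
#' @param m,r_frac approximate-entropy parameters (tolerance as a fraction of
#'   the amplitude-sequence SD).
#' @return named numeric of length 7.
#' @export
amplitude_features <- function(seg, epoch_sd, m = 1, r_frac = 0.2) {
  out <- setNames(rep(NA_real_, 7),
                  c("std_median_peak", "std_median_trough", "apen_peaks",
                    "apen_troughs", "median_peak_trough_diff",
                    "log_pt_ratio_median", "log_pt_ratio_sd"))
  if (nrow(seg$peaks) < 2 || nrow(seg$troughs) < 2) return(out)
  out["std_median_peak"] <- median(seg$peaks$amp) / epoch_sd
  out["std_median_trough"] <- median(seg$troughs$amp) / epoch_sd
  ap <- function(a) {
    if (length(a) <= m + 1) return(NA_real_)
    s <- sd(a)
    if (s == 0) return(0)
    approx_entropy(a, m, r_frac * s)
  }
  out["apen_peaks"] <- ap(seg$peaks$amp)
  out["apen_troughs"] <- ap(seg$troughs$amp)
  k <- min(nrow(seg$peaks), nrow(seg$troughs))
  pk <- seg$peaks$amp[seq_len(k)]; tr <- seg$troughs$amp[seq_len(k)]
  out["median_peak_trough_diff"] <- median(pk - tr)
  ok <- pk > 0 & tr != 0
  if (sum(ok) >= 2) {
    lr <- log(pk[ok] / abs(tr[ok]))
    out["log_pt_ratio_median"] <- median(lr)
    out["log_pt_ratio_sd"] <- sd(lr)
  }
  out
}

#' Flow and volume proxies per breath
#'
#' Uncalibrated effort-signal proxies: per-breath volumes are trapezoidal
#' integrals of |effort - limb trough baseline| over the full cycle, inhale
#' limb and exhale limb; flows are limb amplitude / limb duration. Medians
#' across breaths, inhale:exhale time and flow-rate ratios (both as ratio of
#' medians and median of per-breath ratios), and mean/SD/first-to-last delta
#' of the per-breath amplitude ratio.
#'
#' @inheritParams breath_correlation
#' @return named numeric of length 13.
#' @export
flow_volume_features <- function(x, fs, seg) {
  nm <- c("vol_cycle_median", "vol_inhale_median", "vol_exhale_median",
          "flow_cycle_median", "flow_inhale_median", "flow_exhale_median",
          "ie_time_ratio", "ie_flow_ratio", "amp_ratio_mean", "amp_ratio_sd",
          "amp_ratio_delta", "ie_time_ratio_breath", "ie_flow_ratio_breath")
  out <- setNames(rep(NA_real_, length(nm)), nm)
  b <- seg$breaths
  if (nrow(b) < 2) return(out)
  tt <- (seq_along(x) - 1) / fs
  # breath boundaries fall on sample times by construction
  y0 <- approx(tt, x, xout = b$t0)$y
  y1 <- approx(tt, x, xout = b$t1)$y
  i0 <- round(b$t0 * fs) + 1L
  ip <- round(b$tp * fs) + 1L
  i1 <- round(b$t1 * fs) + 1L
  vin <- vex <- numeric(nrow(b))
  for (i in seq_len(nrow(b))) {
    vin[i] <- trapz(tt[i0[i]:ip[i]], abs(x[i0[i]:ip[i]] - y0[i]))
    vex[i] <- trapz(tt[ip[i]:i1[i]], abs(x[ip[i]:i1[i]] - y1[i]))
  }
  flow_in <- b$amp_in / b$ti
  flow_ex <- b$amp_ex / b$te
  amp_total <- b$amp_in + b$amp_ex
  out["vol_cycle_median"] <- median(vin + vex)
  out["vol_inhale_median"] <- median(vin)
  out["vol_exhale_median"] <- median(vex)
  out["flow_cycle_median"] <- median(amp_total / b$period)
  out["flow_inhale_median"] <- median(flow_in)
  out["flow_exhale_median"] <- median(flow_ex)
  out["ie_time_ratio"] <- median(b$ti) / median(b$te)
  if (median(flow_ex) != 0)
    out["ie_flow_ratio"] <- median(flow_in) / median(flow_ex)
  ok <- b$amp_ex > 0
  if (sum(ok) >= 2) {
    ar <- b$amp_in[ok] / b$amp_ex[ok]
    out["amp_ratio_mean"] <- mean(ar)
    out["amp_ratio_sd"] <- sd(ar)
    out["amp_ratio_delta"] <- ar[length(ar)] - ar[1]
  }
  out["ie_time_ratio_breath"] <- median(b$ti / b$te)
  okf <- flow_ex != 0
  if (any(okf)) out["ie_flow_ratio_breath"] <- median(flow_in[okf] / flow_ex[okf])
  out
}

#' Respiratory regularity (sample entropy)
#'
#' SampEn of the effort signal downsampled to \code{target_hz}, with m = 2
#' and r = 0.2 SD; 0 for a constant epoch.
#'
#' @param x epoch samples.
#' @param fs sampling rate.
#' @param target_hz downsampling target.
#' @param m,r_frac sample-entropy parameters.
#' @export
resp_regularity <- function(x, fs, target_hz = 2, m = 2, r_frac = 0.2) {
  dec <- max(1L, round(fs / target_hz))
  xz <- x[seq(1, length(x), by = dec)]
  s <- sd(xz)
  if (s == 0) return(0)
  sample_entropy(xz, m, r_frac * s)
}

#' Extract the 41 respiratory features for one epoch
#'
#' @param epoch an epoch from [epochize()].
#' @param config a [feature_config()].
#' @return named numeric vector of length 41 in registry order; breath-based
#'   features are \code{NA} when segmentation finds no usable breaths.
#' @export
extract_respiratory <- function(epoch, config = feature_config()) {
  x <- epoch$resp; fs <- epoch$fs_resp
  v <- setNames(rep(NA_real_, length(resp_feature_names)), resp_feature_names)
  s <- sd(x)
  seg <- segment_breaths(x, fs,
                         min_prominence = config$breath_min_prominence_frac * s,
                         min_period = config$breath_min_period)
  rf <- rate_features(seg)
  v[names(rf)] <- rf
  bc <- breath_correlation(x, fs, seg, config$breath_resample_n)
  v[names(bc)] <- bc
  sp <- resp_spectral_features(x, fs, config$resp_bands)
  v[names(sp)] <- sp
  af <- amplitude_features(seg, epoch_sd = if (s > 0) s else NA_real_,
                           m = config$apen_m, r_frac = config$apen_r_frac)
  v[names(af)] <- af
  fv <- flow_volume_features(x, fs, seg)
  v[names(fv)] <- fv
  v["resp_sampen"] <- resp_regularity(x, fs, config$resp_sampen_hz,
                                      config$sampen_m, config$sampen_r_frac)
  v[resp_feature_names]
}
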