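#' Feature-extraction configuration
#'
#' All tunable parameters of the 91-feature extractor. Defaults follow
#' neonatal HRV convention for the band edges and standard practice for the
#' entropy parameters; every value is documented in the methods vignette.
#'
#' @param rr_range physiological RR-interval range in ms; intervals outside
#'   are excluded from HRV statistics.
#' @param hrv_bands named list of HRV band edges in Hz (VLF/LF/HF/sHF/uHF).
#' @param hrv_interp_hz uniform resampling rate for the RR tachogram.
#' @param sampen_m,sampen_r_frac sample-entropy template length and tolerance
#'   as a fraction of the series SD.
#' @param sampen_auc_grid tolerance grid (fractions of SD) for the SampEn
#'   area under the curve.
#' @param decel_theta fractional RR prolongation defining a deceleration.
#' @param decel_window running-median baseline window, beats.
#' @param decel_min_run minimum run length, beats.
#' @param lz_ecg_hz ECG is decimated to this rate before Lempel-Ziv parsing.
#' @param resp_bands respiratory spectral band edges in Hz.
#' @param breath_min_prominence_frac minimum breath extremum prominence as a
#'   fraction of the epoch SD.
#' @param breath_min_period minimum breath period, s.
#' @param breath_resample_n common length to which breaths are resampled for
#'   breath-by-breath correlation.
#' @param apen_m,apen_r_frac approximate-entropy parameters for the
#'   peak/trough amplitude sequences.
#' @param resp_sampen_hz respiration is downsampled to this rate for the
#'   regularity SampEn.
#' @param ewma_alpha smoothing weight for the across-epoch motion-count EWMA.
#' @param cri_min_beats minimum R peaks per epoch for CRI features.
#' @param vg_time_axis \code{"real"} uses R-peak times as the visibility-graph
#'   time axis; \code{"index"} uses the beat index.
#' @return an object of class \code{feature_config}.
#' @export
feature_config <- function(rr_range = c(200, 750),
                           hrv_bands = list(vlf = c(0.01, 0.04),
                                            lf = c(0.04, 0.2),
                                            hf = c(0.2, 1.0),
                                            shf = c(1.0, 1.5),
                                            uhf = c(1.5, 2.0)),
                           hrv_interp_hz = 4,
                           sampen_m = 2, sampen_r_frac = 0.2,
                           sampen_auc_grid = c(0.10, 0.15, 0.20, 0.25, 0.30),
                           decel_theta = 0.1, decel_window = 15,
                           decel_min_run = 2,
                           lz_ecg_hz = 125,
                           resp_bands = list(vlf = c(0.01, 0.05),
                                             lf = c(0.05, 0.15),
                                             hf = c(0.15, 0.5)),
                           breath_min_prominence_frac = 0.2,
                           breath_min_period = 0.5,
                           breath_resample_n = 40,
                           apen_m = 1, apen_r_frac = 0.2,
                           resp_sampen_hz = 2,
                           ewma_alpha = 0.3,
                           cri_min_beats = 4,
                           vg_time_axis = c("real", "index")) {
  structure(list(rr_range = rr_range, hrv_bands = hrv_bands,
                 hrv_interp_hz = hrv_interp_hz, sampen_m = sampen_m,
                 sampen_r_frac = sampen_r_frac,
                 sampen_auc_grid = sampen_auc_grid,
                 decel_theta = decel_theta, decel_window = decel_window,
                 decel_min_run = decel_min_run, lz_ecg_hz = lz_ecg_hz,
                 resp_bands = resp_bands,
                 breath_min_prominence_frac = breath_min_prominence_frac,
                 breath_min_period = breath_min_period,
                 breath_resample_n = breath_resample_n,
                 apen_m = apen_m, apen_r_frac = apen_r_frac,
                 resp_sampen_hz = resp_sampen_hz, ewma_alpha = ewma_alpha,
                 cri_min_beats = cri_min_beats,
                 vg_time_axis = match.arg(vg_time_axis)),
            class = "feature_config")
}
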