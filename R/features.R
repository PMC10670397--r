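#' Feature registry
#'
#' Machine-readable inventory of the 91 features: 34 cardiac, 41 respiratory,
#' 8 CRI-network and 8 motion features, with family, description and units.
#'
#' @return data frame with columns \code{name}, \code{family},
#'   \code{description}, \code{units}.
#' @export
feature_registry <- function() {
  card_desc <- c(
    "number of R peaks in the epoch",
    "mean RR interval", "median RR interval", "SD of RR intervals (SDNN)",
    "coefficient of variation of RR", "minimum RR", "maximum RR",
    "RR range", "RR interquartile range",
    "root mean square of successive RR differences",
    "SD of successive RR differences",
    "fraction of successive RR differences > 20 ms",
    "fraction of successive RR differences > 50 ms",
    "mean heart rate", "SD of heart rate",
    "HRV spectral power, VLF band", "HRV spectral power, LF band",
    "HRV spectral power, HF band", "HRV spectral power, extended sHF band",
    "HRV spectral power, extended uHF band",
    "total HRV spectral power over all five bands",
    "LF/HF power ratio", "normalized LF power LF/(LF+HF)",
    "normalized HF power HF/(LF+HF)",
    "ECG line length over the epoch",
    "mean ECG line length over 1-s sub-windows",
    "SD of ECG line length over 1-s sub-windows",
    "fraction of beats inside heart-rate decelerations",
    "mean maximum fractional RR excess over decelerations",
    "sample entropy of the RR series",
    "area under the SampEn(r) curve of the RR series",
    "quadratic sample entropy of the RR series",
    "Lempel-Ziv complexity of the (decimated, binarized) ECG",
    "Lempel-Ziv complexity of the RR series")
  card_units <- c("count", rep("ms", 8), "ms", "ms", "fraction", "fraction",
                  "bpm", "bpm", rep("ms^2", 6), "ratio", "ratio", "ratio",
                  "au", "au", "au", "fraction", "ratio", "nats", "nats*ms",
                  "nats", "norm. phrases", "norm. phrases")
  resp_desc <- c(
    "variance of instantaneous breath frequency",
    "median instantaneous breath frequency",
    "SD of instantaneous breath frequency",
    "log breaths per minute",
    "mean absolute breath-frequency change per second",
    "mean breath-by-breath correlation", "SD of breath-by-breath correlation",
    "minimum breath-by-breath correlation",
    "maximum breath-by-breath correlation",
    "log respiratory power, VLF band", "log respiratory power, LF band",
    "log respiratory power, HF band",
    "normalized respiratory power, VLF band",
    "normalized respiratory power, LF band",
    "normalized respiratory power, HF band",
    "respiratory VLF/HF power ratio", "respiratory LF/HF power ratio",
    "total respiratory spectral power",
    "dominant respiratory frequency", "log power at the dominant frequency",
    "standardized median peak amplitude",
    "standardized median trough amplitude",
    "approximate entropy of peak amplitudes",
    "approximate entropy of trough amplitudes",
    "median per-breath peak-to-trough difference",
    "median log peak/|trough| amplitude ratio",
    "SD of log peak/|trough| amplitude ratio",
    "median breath-cycle volume proxy", "median inhalation volume proxy",
    "median exhalation volume proxy", "median breath-cycle flow proxy",
    "median inhalation flow proxy", "median exhalation flow proxy",
    "inhale:exhale time ratio (ratio of medians)",
    "inhale:exhale flow-rate ratio (ratio of medians)",
    "mean per-breath amplitude ratio", "SD of per-breath amplitude ratio",
    "first-to-last change of the per-breath amplitude ratio",
    "sample entropy of the 2-Hz effort signal",
    "inhale:exhale time ratio (median of per-breath ratios)",
    "inhale:exhale flow-rate ratio (median of per-breath ratios)")
  resp_units <- c("Hz^2", "Hz", "Hz", "log(1/min)", "Hz/s", rep("r", 4),
                  rep("log au", 3), rep("fraction", 3), "ratio", "ratio",
                  "au", "Hz", "log au", "SD units", "SD units", "nats",
                  "nats", "au", "log ratio", "log ratio", rep("au*s", 3),
                  rep("au/s", 3), "ratio", "ratio", "ratio", "ratio",
                  "ratio", "nats", "ratio", "ratio")
  cri_desc <- c("mean visibility-graph degree", "SD of visibility-graph degree",
                "mean degree of the differenced-series visibility graph",
                "SD of degree of the differenced-series visibility graph",
                "degree assortativity of the visibility graph",
                "mean local clustering coefficient",
                "SD of local clustering coefficient",
                "sample entropy of the degree sequence")
  mot_desc <- c("mean motion value in the epoch", "SD of motion values",
                "sum of motion values",
                "EWMA-smoothed count of nonzero motion values",
                "25th percentile of motion values",
                "50th percentile of motion values",
                "75th percentile of motion values",
                "95th percentile of motion values")
  rbind(
    data.frame(name = cardiac_feature_names, family = "cardiac",
               description = card_desc, units = card_units),
    data.frame(name = resp_feature_names, family = "respiratory",
               description = resp_desc, units = resp_units),
    data.frame(name = cri_feature_names, family = "cri",
               description = cri_desc,
               units = c("edges", "edges", "edges", "edges", "r",
                         "fraction", "fraction", "nats")),
    data.frame(name = motion_feature_names, family = "motion",
               description = mot_desc,
               units = c(rep("au", 3), "count", rep("au", 4)))
  )
}

#' Names of the features in a family subset
#'
#' @param families subset of \code{c("cardiac", "respiratory", "cri",
#'   "motion")}.
#' @export
feature_names <- function(families = c("cardiac", "respiratory", "cri",
                                       "motion")) {
  reg <- feature_registry()
  reg$name[reg$family %in% families]
}

#' Extract the full 91-feature matrix for one recording
#'
#' Preprocesses the recording (per-recording z-scoring, label merging),
#' epochizes it, and extracts the four feature families per epoch. The
#' motion-count EWMA carries across retained epochs in temporal order.
#' Missing values propagate as \code{NA}; imputation happens per
#' cross-validation fold during modeling, never here.
#'
#' @param rec a \code{sleep_recording}.
#' @param config a [feature_config()].
#' @return data frame: \code{subject_id}, \code{epoch_index}, \code{label},
#'   then 91 feature columns.
#' @export
extract_features <- function(rec, config = feature_config()) {
  rec <- preprocess_recording(rec)
  eps <- epochize(rec)
  if (!length(eps))
    return(cbind(data.frame(subject_id = character(0),
                            epoch_index = integer(0), label = character(0)),
                 as.data.frame(matrix(numeric(0), 0, 91,
                                      dimnames = list(NULL, feature_names())))))
  rows <- vector("list", length(eps))
  prev_count <- NULL
  for (k in seq_along(eps)) {
    ep <- eps[[k]]
    mot <- extract_motion(ep, prev_count = prev_count, config = config)
    prev_count <- mot[["motion_count"]]
    rows[[k]] <- c(extract_cardiac(ep, config),
                   extract_respiratory(ep, config),
                   extract_cri(ep, config), mot)
  }
  feat <- do.call(rbind, rows)
  cbind(data.frame(subject_id = rec$subject_id,
                   epoch_index = vapply(eps, `[[`, 0L, "index"),
                   label = vapply(eps, `[[`, "", "label"),
                   stringsAsFactors = FALSE),
        as.data.frame(feat))
}

#' Assemble the feature matrix for a cohort
#'
#' @param recordings list of \code{sleep_recording} objects.
#' @param config a [feature_config()].
#' @return combined feature data frame (see [extract_features()]).
#' @export
assemble_features <- function(recordings, config = feature_config()) {
  out <- do.call(rbind, lapply(recordings, extract_features, config = config))
  key <- paste(out$subject_id, out$epoch_index)
  if (anyDuplicated(key)) stop("duplicate subject/epoch keys")
  rownames(out) <- NULL
  out
}
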