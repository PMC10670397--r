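#' Construct a multimodal sleep recording
#'
#' Container for one subject's simultaneously recorded channels and per-epoch
#' sleep-state annotations. Any of the ECG waveform or the R-peak train may be
#' absent (R peaks are detected from ECG when needed and possible).
#'
#' @param subject_id subject identifier.
#' @param ecg ECG waveform or \code{NULL}.
#' @param fs_ecg ECG sampling rate, Hz.
#' @param resp respiratory effort waveform.
#' @param fs_resp respiration sampling rate, Hz.
#' @param motion motion-count trace.
#' @param fs_motion motion sampling rate, Hz.
#' @param rpeaks R-peak times in seconds, or \code{NULL}.
#' @param annotations data frame with columns \code{epoch_index},
#'   \code{onset_s}, \code{label} (labels from AS, QS, Wake, Caretaking,
#'   Unknown, or the merged CTW).
#' @return an object of class \code{sleep_recording}.
#' @export
new_recording <- function(subject_id, ecg = NULL, fs_ecg = 500,
                          resp, fs_resp = 16, motion, fs_motion = 8,
                          rpeaks = NULL, annotations) {
  stopifnot(is.data.frame(annotations),
            all(c("epoch_index", "onset_s", "label") %in% names(annotations)))
  rec <- structure(list(subject_id = subject_id,
                        ecg = ecg, fs_ecg = fs_ecg,
                        resp = resp, fs_resp = fs_resp,
                        motion = motion, fs_motion = fs_motion,
                        rpeaks = rpeaks, annotations = annotations,
                        normalized = FALSE),
                   class = "sleep_recording")
  durs <- c(resp = length(resp) / fs_resp, motion = length(motion) / fs_motion)
  if (!is.null(ecg)) durs <- c(durs, ecg = length(ecg) / fs_ecg)
  if (diff(range(durs)) > 30)
    stop("channel durations disagree by more than one epoch")
  rec
}

#' @export
print.sleep_recording <- function(x, ...) {
  cat(sprintf("<sleep_recording> subject %s: %.1f min, %d annotated epochs\n",
              x$subject_id, length(x$resp) / x$fs_resp / 60,
              nrow(x$annotations)))
  cat(sprintf("  channels: %sresp @%g Hz, motion @%g Hz%s\n",
              if (!is.null(x$ecg)) sprintf("ecg @%g Hz, ", x$fs_ecg) else "",
              x$fs_resp, x$fs_motion,
              if (!is.null(x$rpeaks)) sprintf(", %d R peaks", length(x$rpeaks))
              else ""))
  invisible(x)
}

#' Write / read a recording
#'
#' \code{write_recording} stores the channels either as per-channel CSV files
#' (\code{time,value}) or as one EDF file, plus CSV sidecars for the
#' annotations (\code{epoch_index,onset_s,label}) and, when present, the
#' R-peak times. \code{read_recording} reverses the process.
#'
#' @param rec a \code{sleep_recording}.
#' @param dir output directory (created if needed).
#' @param format \code{"csv"} or \code{"edf"}. EDF stores samples as 16-bit
#'   integers, so the EDF round trip is exact only to quantization.
#' @return \code{write_recording}: the directory, invisibly.
#'   \code{read_recording}: a \code{sleep_recording}.
#' @export
write_recording <- function(rec, dir, format = c("csv", "edf")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, rec$subject_id)
  if (format == "csv") {
    chans <- list(ecg = c("ecg", "fs_ecg"), resp = c("resp", "fs_resp"),
                  motion = c("motion", "fs_motion"))
    for (nm in names(chans)) {
      x <- rec[[chans[[nm]][1]]]
      if (is.null(x)) next
      fs <- rec[[chans[[nm]][2]]]
      write.csv(data.frame(time = (seq_along(x) - 1) / fs, value = x),
                sprintf("%s_%s.csv", base, nm), row.names = FALSE)
    }
  } else {
    sigs <- list(list(label = "RESP", fs = rec$fs_resp, data = rec$resp),
                 list(label = "MOTION", fs = rec$fs_motion, data = rec$motion))
    if (!is.null(rec$ecg))
      sigs <- c(list(list(label = "ECG", fs = rec$fs_ecg, data = rec$ecg)),
                sigs)
    write_edf(sigs, paste0(base, ".edf"), patient_id = rec$subject_id)
  }
  write.csv(rec$annotations, paste0(base, "_annotations.csv"),
            row.names = FALSE)
  if (!is.null(rec$rpeaks))
    write.csv(data.frame(time_s = rec$rpeaks), paste0(base, "_rpeaks.csv"),
              row.names = FALSE)
  invisible(dir)
}

#' @rdname write_recording
#' @param subject_id subject whose files to read from \code{dir}.
#' @export
read_recording <- function(dir, subject_id, format = c("csv", "edf")) {
  format <- match.arg(format)
  base <- file.path(dir, subject_id)
  ann_path <- paste0(base, "_annotations.csv")
  if (!file.exists(ann_path))
    stop("missing annotation file: ", ann_path)
  ann <- read.csv(ann_path, stringsAsFactors = FALSE)
  rpk_path <- paste0(base, "_rpeaks.csv")
  rpk <- if (file.exists(rpk_path)) read.csv(rpk_path)$time_s else NULL
  if (format == "csv") {
    readc <- function(nm) {
      p <- sprintf("%s_%s.csv", base, nm)
      if (!file.exists(p)) return(NULL)
      df <- read.csv(p)
      list(x = df$value, fs = round(1 / median(diff(df$time))))
    }
    ecg <- readc("ecg"); resp <- readc("resp"); mot <- readc("motion")
    if (is.null(resp) || is.null(mot))
      stop("missing respiration or motion channel for ", subject_id)
    new_recording(subject_id, ecg = ecg$x, fs_ecg = ecg$fs %||% 500,
                  resp = resp$x, fs_resp = resp$fs,
                  motion = mot$x, fs_motion = mot$fs,
                  rpeaks = rpk, annotations = ann)
  } else {
    edf <- read_edf(paste0(base, ".edf"))
    get <- function(lab) {
      i <- match(lab, vapply(edf$signals, `[[`, "", "label"))
      if (is.na(i)) NULL else edf$signals[[i]]
    }
    ecg <- get("ECG"); resp <- get("RESP"); mot <- get("MOTION")
    if (is.null(resp) || is.null(mot))
      stop("EDF file lacks RESP/MOTION channels for ", subject_id)
    new_recording(subject_id,
                  ecg = ecg$data, fs_ecg = if (!is.null(ecg)) ecg$fs else 500,
                  resp = resp$data, fs_resp = resp$fs,
                  motion = mot$data, fs_motion = mot$fs,
                  rpeaks = rpk, annotations = ann)
  }
}

#' Z-score normalization
#'
#' Rescales a series to zero mean and unit standard deviation. Applied once
#' per recording (never per epoch) before feature extraction.
#'
#' @param x numeric series of length >= 2 with nonzero variance.
#' @return normalized series.
#' @export
zscore_normalize <- function(x) {
  if (length(x) < 2) stop("series too short to normalize")
  s <- sd(x)
  if (s == 0) stop("cannot z-score a constant series")
  (x - mean(x)) / s
}

#' Merge annotation labels into the three analysis classes
#'
#' Wake and Caretaking epochs are merged into CTW; Unknown epochs are flagged
#' for exclusion (returned as \code{NA}); AS and QS pass through.
#'
#' @param labels character vector from \{AS, QS, Wake, Caretaking, Unknown,
#'   CTW\}; \code{NA} passes through.
#' @return character vector over \{AS, QS, CTW\} with \code{NA} marking
#'   excluded epochs.
#' @export
merge_labels <- function(labels) {
  map <- c(AS = "AS", QS = "QS", Wake = "CTW", Caretaking = "CTW",
           CTW = "CTW", Unknown = NA_character_)
  bad <- setdiff(unique(labels[!is.na(labels)]), names(map))
  if (length(bad)) stop("unrecognized label(s): ", paste(bad, collapse = ", "))
  unname(map[labels])
}

#' Normalize signals and merge labels for one recording
#'
#' Applies per-recording z-score normalization to the ECG and respiratory
#' channels (the motion-count trace keeps its natural nonnegative scale) and
#' merges annotation labels via [merge_labels()].
#'
#' @param rec a \code{sleep_recording}.
#' @return the preprocessed recording.
#' @export
preprocess_recording <- function(rec) {
  if (!rec$normalized) {
    if (!is.null(rec$ecg)) rec$ecg <- zscore_normalize(rec$ecg)
    rec$resp <- zscore_normalize(rec$resp)
    rec$normalized <- TRUE
  }
  rec$annotations$label <- merge_labels(rec$annotations$label)
  rec
}

#' Cut a recording into 30-s epochs
#'
#' One epoch per retained annotation row; Unknown (excluded) epochs and any
#' trailing partial window are dropped. Epoch windows are half-open
#' \code{[30i, 30(i+1))} seconds with 0-based indices, so no sample belongs to
#' two epochs.
#'
#' @param rec a preprocessed \code{sleep_recording} (see
#'   [preprocess_recording()]).
#' @return list of epochs, each with \code{index}, \code{label}, per-channel
#'   sample slices, and the R-peak times falling in the window (seconds from
#'   epoch start).
#' @export
epochize <- function(rec) {
  n_full <- floor(length(rec$resp) / (30 * rec$fs_resp))
  ann <- rec$annotations
  if (nrow(ann) > n_full + 1)
    stop("annotation/signal length mismatch beyond one epoch")
  ann <- ann[ann$epoch_index < n_full & !is.na(ann$label), , drop = FALSE]
  rpk <- rec$rpeaks
  if (is.null(rpk) && !is.null(rec$ecg))
    rpk <- detect_rpeaks(rec$ecg, rec$fs_ecg)
  slice <- function(x, fs, i) {
    if (is.null(x)) return(NULL)
    x[(i * 30 * fs + 1):((i + 1) * 30 * fs)]
  }
  lapply(seq_len(nrow(ann)), function(r) {
    i <- ann$epoch_index[r]
    rp <- if (!is.null(rpk)) rpk[rpk >= 30 * i & rpk < 30 * (i + 1)] - 30 * i
          else numeric(0)
    list(index = i, label = ann$label[r],
         ecg = slice(rec$ecg, rec$fs_ecg, i), fs_ecg = rec$fs_ecg,
         resp = slice(rec$resp, rec$fs_resp, i), fs_resp = rec$fs_resp,
         motion = slice(rec$motion, rec$fs_motion, i),
         fs_motion = rec$fs_motion, rpeaks = rp)
  })
}

#' Detect R peaks in an ECG trace
#'
#' Pan-Tompkins-style detector: 5-40 Hz band-pass, squared derivative,
#' 120-ms moving-window integration, adaptive threshold, and a 200-ms
#' refractory period. Detections are refined to the band-passed signal's
#' local maximum within +/- 50 ms.
#'
#' @param ecg ECG samples.
#' @param fs sampling rate, Hz (>= 250 recommended).
#' @return strictly increasing R-peak times in seconds; empty for a flat
#'   signal.
#' @export
detect_rpeaks <- function(ecg, fs) {
  if (length(ecg) < fs || sd(ecg) == 0) return(numeric(0))
  bf <- signal::butter(3, c(5, 40) / (fs / 2), type = "pass")
  filt <- signal::filtfilt(bf, ecg)
  sq <- c(0, diff(filt))^2
  w <- max(3L, as.integer(round(0.12 * fs)))
  int <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  int[is.na(int)] <- 0
  thr <- 0.25 * quantile(int, 0.995, names = FALSE)
  if (thr <= 0) return(numeric(0))
  above <- int > thr
  # candidate = argmax of the integrated signal within each run above threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- integer(0)
  for (k in which(r$values)) {
    seg <- starts[k]:ends[k]
    cand <- c(cand, seg[which.max(int[seg])])
  }
  if (!length(cand)) return(numeric(0))
  # refine to the band-passed local maximum within +/- 50 ms
  half <- as.integer(round(0.05 * fs))
  cand <- vapply(cand, function(i) {
    lo <- max(1L, i - half); hi <- min(length(filt), i + half)
    lo + which.max(filt[lo:hi]) - 1L
  }, integer(1))
  cand <- sort(unique(cand))
  # refractory: within 200 ms keep the larger peak
  refr <- 0.2 * fs
  keep <- integer(0)
  for (i in cand) {
    if (length(keep) && i - keep[length(keep)] < refr) {
      if (filt[i] > filt[keep[length(keep)]]) keep[length(keep)] <- i
    } else keep <- c(keep, i)
  }
  (keep - 1) / fs
}
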