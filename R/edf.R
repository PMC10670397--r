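# Minimal EDF (European Data Format) support: continuous recordings,
# 1-second data records, 16-bit samples. Sufficient for the ECG/RESP/MOTION
# channel bundle written by the simulator; annotations travel in a CSV
# sidecar rather than EDF+ TAL blocks.

pad <- function(s, n) {
  s <- substr(as.character(s), 1, n)
  sprintf(paste0("%-", n, "s"), s)
}

#' Write signals to an EDF file
#'
#' @param signals list of channels, each \code{list(label, fs, data)} with an
#'   integer per-second sampling rate; all channels must span the same whole
#'   number of seconds.
#' @param path output file.
#' @param patient_id,recording_id free-text header fields.
#' @return \code{path}, invisibly.
#' @export
write_edf <- function(signals, path, patient_id = "X", recording_id = "X") {
  ns <- length(signals)
  fss <- vapply(signals, `[[`, 0, "fs")
  if (any(fss != round(fss))) stop("EDF writer requires integer Hz rates")
  durs <- vapply(signals, function(s) length(s$data) / s$fs, 0)
  if (diff(range(durs)) > 1e-9 || durs[1] != round(durs[1]))
    stop("all channels must span the same whole number of seconds")
  n_rec <- as.integer(durs[1])
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad("0", 8), pad(patient_id, 80), pad(recording_id, 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256 * (ns + 1), 8), pad("", 44), pad(n_rec, 8), pad(1, 8), pad(ns, 4)
  ), con, eos = NULL)
  scl <- lapply(signals, function(s) {
    pmin <- min(s$data); pmax <- max(s$data)
    if (pmax == pmin) pmax <- pmin + 1
    list(pmin = pmin, pmax = pmax)
  })
  fld <- function(f, n) writeChar(paste0(vapply(seq_len(ns), f, "")),
                                  con, eos = NULL)
  fld(function(i) pad(signals[[i]]$label, 16), 16)
  fld(function(i) pad("", 80), 80)
  fld(function(i) pad("au", 8), 8)
  fld(function(i) pad(formatC(scl[[i]]$pmin, digits = 6, format = "g"), 8), 8)
  fld(function(i) pad(formatC(scl[[i]]$pmax, digits = 6, format = "g"), 8), 8)
  fld(function(i) pad(-32768, 8), 8)
  fld(function(i) pad(32767, 8), 8)
  fld(function(i) pad("", 80), 80)
  fld(function(i) pad(signals[[i]]$fs, 8), 8)
  fld(function(i) pad("", 32), 32)
  # re-read the header's printed physical ranges so scaling is self-consistent
  pr <- lapply(scl, function(s) {
    c(as.numeric(formatC(s$pmin, digits = 6, format = "g")),
      as.numeric(formatC(s$pmax, digits = 6, format = "g")))
  })
  dig <- lapply(seq_len(ns), function(i) {
    rng <- pr[[i]]
    d <- round((signals[[i]]$data - rng[1]) / (rng[2] - rng[1]) * 65535 - 32768)
    as.integer(pmin(pmax(d, -32768), 32767))
  })
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      fs <- signals[[i]]$fs
      writeBin(dig[[i]][((r - 1) * fs + 1):(r * fs)], con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file written by [write_edf()] or any continuous
#'   single-record-duration EDF with 1-s records.
#' @return list with \code{signals}, each \code{list(label, fs, data)}.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8)                                   # version
  rd(80); rd(80); rd(8); rd(8)            # ids, date, time
  rd(8); rd(44)                           # header bytes, reserved
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  g <- function(n) vapply(seq_len(ns), function(i) rd(n), "")
  labels <- trimws(g(16))
  g(80); g(8)
  pmin <- as.numeric(g(8)); pmax <- as.numeric(g(8))
  dmin <- as.numeric(g(8)); dmax <- as.numeric(g(8))
  g(80)
  spr <- as.integer(g(8))
  g(32)
  raw <- vector("list", ns)
  for (i in seq_len(ns)) raw[[i]] <- integer(n_rec * spr[i])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, "integer", spr[i], size = 2, signed = TRUE,
                   endian = "little")
      raw[[i]][((r - 1) * spr[i] + 1):(r * spr[i])] <- v
    }
  }
  signals <- lapply(seq_len(ns), function(i) {
    phys <- pmin[i] + (raw[[i]] - dmin[i]) / (dmax[i] - dmin[i]) *
      (pmax[i] - pmin[i])
    list(label = labels[i], fs = spr[i] / rec_dur, data = phys)
  })
  list(signals = signals)
}
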