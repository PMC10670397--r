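#' State-specific physiology parameters for the recording simulator
#'
#' Bundles the per-state parameters governing simulated cardiac, respiratory
#' and movement dynamics in one sleep state (active sleep AS, quiet sleep QS,
#' or the merged caretaking+wake state CTW).
#'
#' @param mean_rr mean inter-beat (RR) interval, ms.
#' @param sd_rr beat-to-beat RR standard deviation, ms.
#' @param decel_rate heart-rate deceleration events per minute.
#' @param decel_depth fractional RR prolongation during a deceleration
#'   (0.3 means affected intervals are multiplied by 1.3).
#' @param breath_rate breaths per minute.
#' @param breath_rate_jitter coefficient of variation of the breath period.
#' @param breath_amp breath amplitude, arbitrary effort units.
#' @param breath_amp_cv coefficient of variation of breath amplitude.
#' @param motion_burst_rate movement bursts per minute.
#' @param motion_burst_amp typical burst amplitude, arbitrary motion units.
#' @return an object of class \code{state_params}.
#' @export
state_params <- function(mean_rr, sd_rr, decel_rate = 0, decel_depth = 0.3,
                         breath_rate, breath_rate_jitter, breath_amp,
                         breath_amp_cv, motion_burst_rate, motion_burst_amp) {
  p <- list(mean_rr = mean_rr, sd_rr = sd_rr, decel_rate = decel_rate,
            decel_depth = decel_depth, breath_rate = breath_rate,
            breath_rate_jitter = breath_rate_jitter, breath_amp = breath_amp,
            breath_amp_cv = breath_amp_cv,
            motion_burst_rate = motion_burst_rate,
            motion_burst_amp = motion_burst_amp)
  num <- vapply(p, is.numeric, logical(1))
  if (!all(num)) stop("all state parameters must be numeric")
  if (p$mean_rr <= 0) stop("mean_rr must be positive")
  if (p$breath_rate <= 0) stop("breath_rate must be positive")
  if (any(unlist(p) < 0)) stop("rates and amplitudes must be nonnegative")
  structure(p, class = "state_params")
}

# Literature-typical neonatal defaults. Cardiorespiratory parameters separate
# AS from QS strongly but AS from CTW only weakly; movement separates CTW from
# sleep strongly but AS from QS weakly.
default_state_params <- function() {
  list(
    AS = state_params(mean_rr = 380, sd_rr = 24, decel_rate = 0.3,
                      decel_depth = 0.30, breath_rate = 55,
                      breath_rate_jitter = 0.25, breath_amp = 1.0,
                      breath_amp_cv = 0.35, motion_burst_rate = 2,
                      motion_burst_amp = 5),
    QS = state_params(mean_rr = 430, sd_rr = 11, decel_rate = 0.6,
                      decel_depth = 0.35, breath_rate = 48,
                      breath_rate_jitter = 0.08, breath_amp = 0.7,
                      breath_amp_cv = 0.12, motion_burst_rate = 0.4,
                      motion_burst_amp = 3),
    CTW = state_params(mean_rr = 375, sd_rr = 27, decel_rate = 0.2,
                       decel_depth = 0.25, breath_rate = 57,
                       breath_rate_jitter = 0.28, breath_amp = 1.05,
                       breath_amp_cv = 0.40, motion_burst_rate = 12,
                       motion_burst_amp = 10)
  )
}

#' Simulator configuration
#'
#' @param states named list of [state_params()] for AS, QS and CTW.
#' @param fractions target stationary state mix; defaults to the skewed
#'   AS 72% / QS 12% / CTW 16% distribution typical of preterm NICU
#'   recordings.
#' @param bout_means mean state-bout length in 30-s epochs.
#' @param n_epochs recording duration in 30-s epochs.
#' @param fs_ecg,fs_resp,fs_motion channel sampling rates, Hz.
#' @param include_ecg generate the raw ECG waveform (the R-peak train is
#'   always generated).
#' @param ecg_noise_sd baseline ECG noise SD relative to unit QRS amplitude.
#' @param resp_noise_sd additive respiratory noise SD in effort units.
#' @param unknown_frac fraction of epochs relabeled Unknown in the written
#'   annotations (exercises exclusion logic).
#' @param seed integer seed; fully determines simulator output.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(states = default_state_params(),
                       fractions = c(AS = 0.72, QS = 0.12, CTW = 0.16),
                       bout_means = c(AS = 20, QS = 10, CTW = 5),
                       n_epochs = 589, fs_ecg = 500, fs_resp = 16,
                       fs_motion = 8, include_ecg = TRUE,
                       ecg_noise_sd = 0.05, resp_noise_sd = 0.02,
                       unknown_frac = 0, seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("state fractions must sum to 1")
  if (n_epochs < 1) stop("duration must be at least 1 epoch")
  if (!setequal(names(states), c("AS", "QS", "CTW")))
    stop("states must be named AS, QS, CTW")
  fractions <- fractions[c("AS", "QS", "CTW")]
  bout_means <- bout_means[c("AS", "QS", "CTW")]
  if (any(bout_means < 1)) stop("mean bout lengths must be >= 1 epoch")
  structure(list(states = states, fractions = fractions,
                 bout_means = bout_means, n_epochs = as.integer(n_epochs),
                 fs_ecg = fs_ecg, fs_resp = fs_resp, fs_motion = fs_motion,
                 include_ecg = include_ecg, ecg_noise_sd = ecg_noise_sd,
                 resp_noise_sd = resp_noise_sd, unknown_frac = unknown_frac,
                 seed = seed),
            class = "sim_config")
}

# Epoch-level Markov transition matrix with stationary distribution
# `fractions` and geometric bout lengths of the requested means. Off-diagonal
# probability flow is balanced by Sinkhorn scaling.
bout_transition_matrix <- function(fractions, bout_means) {
  k <- length(fractions)
  f <- fractions / bout_means            # per-epoch exit flow out of each state
  M <- outer(f, f)
  diag(M) <- 0
  for (it in 1:200) {
    M <- M * (f / pmax(rowSums(M), .Machine$double.eps))
    M <- t(t(M) * (f / pmax(colSums(M), .Machine$double.eps)))
  }
  P <- M / fractions
  diag(P) <- 1 - rowSums(P)
  if (any(diag(P) < 0)) stop("infeasible fractions / bout-length combination")
  dimnames(P) <- list(names(fractions), names(fractions))
  P
}

#' Generate a synthetic hypnogram
#'
#' Semi-Markov state sequence over 30-s epochs: bout lengths are geometric
#' with the configured means and the long-run state mix matches the
#' configured fractions.
#'
#' @param config a [sim_config()].
#' @param seed optional seed overriding \code{config$seed}; \code{NA} uses
#'   the current RNG state.
#' @return character vector of per-epoch labels (AS/QS/CTW), class
#'   \code{hypnogram} with attribute \code{epoch_s = 30}.
#' @export
generate_hypnogram <- function(config, seed = config$seed) {
  P <- bout_transition_matrix(config$fractions, config$bout_means)
  states <- names(config$fractions)
  with_local_seed(if (is.na(seed[1])) NULL else seed, {
    lab <- character(config$n_epochs)
    cur <- sample(states, 1, prob = config$fractions)
    for (i in seq_len(config$n_epochs)) {
      lab[i] <- cur
      cur <- sample(states, 1, prob = P[cur, ])
    }
    structure(lab, class = "hypnogram", epoch_s = 30)
  })
}

#' Generate R-peak times for a hypnogram
#'
#' Inter-beat intervals are Gaussian with the state-specific mean and SD
#' (truncated positive); deceleration events arrive as a Poisson process and
#' prolong a short run of intervals by the state's \code{decel_depth}.
#'
#' @inheritParams generate_hypnogram
#' @param hypnogram per-epoch state labels.
#' @return strictly increasing R-peak times in seconds from recording start.
#' @export
generate_rpeaks <- function(hypnogram, config, seed = NA) {
  total <- length(hypnogram) * 30
  with_local_seed(if (is.na(seed[1])) NULL else seed, {
    times <- numeric(ceiling(total / 0.05) + 10L)
    n <- 0L
    t <- 0
    decel_left <- 0L
    while (t < total) {
      st <- config$states[[hypnogram[min(floor(t / 30) + 1, length(hypnogram))]]]
      rr <- rnorm(1, st$mean_rr, st$sd_rr) / 1000
      rr <- max(rr, 0.05)
      if (decel_left > 0L) {
        rr <- rr * (1 + st$decel_depth)
        decel_left <- decel_left - 1L
      } else if (st$decel_rate > 0 &&
                 runif(1) < st$decel_rate * rr / 60) {
        decel_left <- sample(3:6, 1)
      }
      t <- t + rr
      if (t >= total) break
      n <- n + 1L
      times[n] <- t
    }
    times[seq_len(n)]
  })
}

#' Generate a respiratory effort waveform
#'
#' Concatenated breath cycles. Each breath's period and amplitude are drawn
#' with the state-specific jitter/CV; the waveform is a smooth asymmetric
#' raised-cosine oscillation (inhale 40% / exhale 60% of the cycle) so that
#' peak, trough and flow features are nontrivial.
#'
#' @inheritParams generate_rpeaks
#' @return numeric waveform sampled at \code{config$fs_resp} Hz, exactly
#'   \code{30 * fs_resp} samples per epoch.
#' @export
generate_respiration <- function(hypnogram, config, seed = NA) {
  total <- length(hypnogram) * 30
  fs <- config$fs_resp
  with_local_seed(if (is.na(seed[1])) NULL else seed, {
    starts <- numeric(0); periods <- numeric(0); amps <- numeric(0)
    t <- 0
    while (t < total) {
      st <- config$states[[hypnogram[min(floor(t / 30) + 1, length(hypnogram))]]]
      per <- 60 / st$breath_rate
      per <- max(per * (1 + st$breath_rate_jitter * rnorm(1)), 0.3)
      amp <- max(st$breath_amp * (1 + st$breath_amp_cv * rnorm(1)), 0.05)
      starts <- c(starts, t); periods <- c(periods, per); amps <- c(amps, amp)
      t <- t + per
    }
    tt <- seq(0, total - 1 / fs, by = 1 / fs)
    idx <- findInterval(tt, starts)
    tau <- tt - starts[idx]
    ti <- 0.4 * periods[idx]
    te <- periods[idx] - ti
    a <- amps[idx]
    y <- ifelse(tau < ti,
                a * (1 - cos(pi * tau / ti)) / 2,
                a * (1 + cos(pi * pmin((tau - ti) / te, 1))) / 2)
    if (config$resp_noise_sd > 0)
      y <- y + rnorm(length(y), 0, config$resp_noise_sd)
    y
  })
}

#' Generate a motion-count trace
#'
#' Movement bursts arrive as a Poisson process at the state-specific rate;
#' each burst is a short Hann-shaped pulse of amplitude near the state's
#' \code{motion_burst_amp}. The series is zero between bursts.
#'
#' @inheritParams generate_rpeaks
#' @return nonnegative series at \code{config$fs_motion} Hz, 30 * fs samples
#'   per epoch.
#' @export
generate_motion <- function(hypnogram, config, seed = NA) {
  fs <- config$fs_motion
  spe <- as.integer(30 * fs)
  n <- length(hypnogram) * spe
  with_local_seed(if (is.na(seed[1])) NULL else seed, {
    y <- numeric(n)
    for (i in seq_along(hypnogram)) {
      st <- config$states[[hypnogram[i]]]
      nb <- rpois(1, st$motion_burst_rate / 2)  # per 30-s epoch
      if (nb == 0) next
      off <- (i - 1L) * spe
      for (b in seq_len(nb)) {
        dur <- runif(1, 0.5, 2)
        len <- max(2L, round(dur * fs))
        s0 <- off + sample.int(spe, 1)
        amp <- st$motion_burst_amp * runif(1, 0.5, 1.5)
        pulse <- amp * (0.5 - 0.5 * cos(2 * pi * seq_len(len) / (len + 1)))
        idx <- s0:min(s0 + len - 1L, n)
        y[idx] <- y[idx] + pulse[seq_along(idx)]
      }
    }
    y
  })
}

#' Generate an ECG-like waveform from R-peak times
#'
#' Baseline Gaussian noise plus a stereotyped QRS-like template (Ricker
#' wavelet, width ~20 ms) centred at each R time; the template peak is the
#' sample-level argmax within +/- 50 ms of each R time.
#'
#' @param rpeak_times strictly increasing R times in seconds.
#' @param config a [sim_config()].
#' @param duration_s total waveform length in seconds.
#' @param seed optional seed (\code{NA} uses the current RNG state).
#' @return numeric waveform at \code{config$fs_ecg} Hz.
#' @export
generate_ecg_waveform <- function(rpeak_times, config, duration_s, seed = NA) {
  fs <- config$fs_ecg
  n <- as.integer(round(duration_s * fs))
  if (length(rpeak_times) && any(diff(rpeak_times) <= 0))
    stop("rpeak_times must be strictly increasing")
  with_local_seed(if (is.na(seed[1])) NULL else seed, {
    y <- if (config$ecg_noise_sd > 0) rnorm(n, 0, config$ecg_noise_sd)
         else numeric(n)
    half <- as.integer(round(0.04 * fs))
    tt <- (-half:half) / fs
    sig <- 0.01
    tmpl <- (1 - (tt / sig)^2) * exp(-tt^2 / (2 * sig^2))
    for (rt in rpeak_times) {
      c0 <- as.integer(round(rt * fs)) + 1L
      idx <- (c0 - half):(c0 + half)
      ok <- idx >= 1L & idx <= n
      y[idx[ok]] <- y[idx[ok]] + tmpl[ok]
    }
    y
  })
}

#' Simulate one annotated multimodal recording
#'
#' Draws a hypnogram and the matching R-peak train, respiratory effort and
#' motion traces (plus, optionally, the raw ECG waveform), and bundles them
#' with a per-epoch annotation table. A configurable fraction of epochs is
#' relabeled Unknown in the annotations to exercise downstream exclusion.
#'
#' @param config a [sim_config()].
#' @param subject_id subject identifier stored with the recording.
#' @param seed overrides \code{config$seed}.
#' @return a \code{sleep_recording} object (see [read_recording()] for the
#'   layout).
#' @export
simulate_recording <- function(config = sim_config(), subject_id = "S1",
                               seed = config$seed) {
  with_local_seed(seed, {
    hyp <- generate_hypnogram(config, seed = NA)
    rpk <- generate_rpeaks(hyp, config, seed = NA)
    resp <- generate_respiration(hyp, config, seed = NA)
    mot <- generate_motion(hyp, config, seed = NA)
    ecg <- if (config$include_ecg)
      generate_ecg_waveform(rpk, config, length(hyp) * 30, seed = NA)
    else NULL
    lab <- as.character(hyp)
    if (config$unknown_frac > 0) {
      nu <- round(config$unknown_frac * length(lab))
      if (nu > 0) lab[sample.int(length(lab), nu)] <- "Unknown"
    }
    ann <- data.frame(epoch_index = seq_along(lab) - 1L,
                      onset_s = (seq_along(lab) - 1L) * 30,
                      label = lab, stringsAsFactors = FALSE)
    new_recording(subject_id = subject_id,
                  ecg = ecg, fs_ecg = config$fs_ecg,
                  resp = resp, fs_resp = config$fs_resp,
                  motion = mot, fs_motion = config$fs_motion,
                  rpeaks = rpk, annotations = ann)
  })
}

#' Simulate a cohort of subjects
#'
#' Each subject gets an independent recording; mild subject-level
#' heterogeneity is added by jittering the state parameters multiplicatively
#' (lognormal, SD \code{subject_sd}), emulating between-infant physiological
#' variability so that leave-one-subject-out evaluation is meaningful.
#'
#' @param n_subjects number of subjects.
#' @param config base [sim_config()].
#' @param seed cohort seed; per-subject seeds are derived deterministically.
#' @param subject_sd fractional between-subject parameter jitter.
#' @return list of \code{sleep_recording} objects.
#' @export
simulate_cohort <- function(n_subjects = 8, config = sim_config(),
                            seed = config$seed, subject_sd = 0.08) {
  jitter_fields <- c("mean_rr", "sd_rr", "breath_rate", "breath_amp",
                     "motion_burst_rate", "motion_burst_amp")
  out <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    si <- (seed + 7919L * i) %% .Machine$integer.max
    cfg <- config
    if (subject_sd > 0) {
      cfg$states <- with_local_seed(si, {
        lapply(config$states, function(st) {
          for (f in jitter_fields)
            st[[f]] <- st[[f]] * exp(rnorm(1, 0, subject_sd))
          st
        })
      })
    }
    out[[i]] <- simulate_recording(cfg, subject_id = sprintf("S%d", i),
                                   seed = si + 1L)
  }
  out
}
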