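# Deterministic single-state recording, bypassing the Markov hypnogram so
# that tests can probe one state's physiology in isolation.
state_recording <- function(state, n_epochs, seed, include_ecg = TRUE,
                            decel_rate = NULL) {
  cfg <- sim_config(n_epochs = n_epochs, seed = seed,
                    include_ecg = include_ecg)
  if (!is.null(decel_rate))
    for (s in names(cfg$states)) cfg$states[[s]]$decel_rate <- decel_rate
  hyp <- structure(rep(state, n_epochs), class = "hypnogram", epoch_s = 30)
  rpk <- generate_rpeaks(hyp, cfg, seed = seed)
  resp <- generate_respiration(hyp, cfg, seed = seed + 1L)
  mot <- generate_motion(hyp, cfg, seed = seed + 2L)
  ecg <- if (include_ecg)
    generate_ecg_waveform(rpk, cfg, n_epochs * 30, seed = seed + 3L)
  else NULL
  ann <- data.frame(epoch_index = seq_len(n_epochs) - 1L,
                    onset_s = (seq_len(n_epochs) - 1L) * 30,
                    label = state, stringsAsFactors = FALSE)
  new_recording("SX", ecg = ecg, fs_ecg = cfg$fs_ecg,
                resp = resp, fs_resp = cfg$fs_resp,
                motion = mot, fs_motion = cfg$fs_motion,
                rpeaks = rpk, annotations = ann)
}

state_epoch <- function(state, seed, n_epochs = 1) {
  epochize(preprocess_recording(state_recording(state, n_epochs, seed)))[[1]]
}
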