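# a clean synthetic breathing epoch with known geometry
cosine_epoch <- function(fs = 16, dur = 30, period = 1.25, amp = 1,
                         phase = 0) {
  tt <- seq(0, dur - 1 / fs, by = 1 / fs)
  amp * sin(2 * pi * tt / period + phase)
}

test_that("segment_breaths recovers the breaths of a pure oscillation", {
  fs <- 16; period <- 1.25
  x <- cosine_epoch(fs, period = period)
  seg <- segment_breaths(x, fs)
  # 30 s / 1.25 s = 24 cycles; interior trough-peak-trough triples ~ 23
  expect_gt(nrow(seg$breaths), 20)
  expect_lt(nrow(seg$breaths), 25)
  expect_equal(median(seg$breaths$period), period, tolerance = 2 / fs)
  expect_true(all(seg$breaths$amp_in > 0))
  expect_true(all(seg$breaths$amp_ex > 0))
  # peaks near +1, troughs near -1
  expect_equal(median(seg$peaks$amp), 1, tolerance = 0.05)
  expect_equal(median(seg$troughs$amp), -1, tolerance = 0.05)
})

test_that("segment_breaths prunes sub-prominence wiggles", {
  fs <- 16
  x <- cosine_epoch(fs, period = 2)
  set.seed(61)
  noisy <- x + 0.05 * sin(2 * pi * seq_along(x) / 3)
  seg_c <- segment_breaths(x, fs)
  seg_n <- segment_breaths(noisy, fs, min_prominence = 0.2 * sd(noisy))
  expect_equal(nrow(seg_n$breaths), nrow(seg_c$breaths), tolerance = 2)
  # degenerate inputs yield the empty segmentation
  expect_equal(nrow(segment_breaths(rep(1, 480), fs)$breaths), 0)
  expect_equal(nrow(segment_breaths(rnorm(10), fs)$breaths), 0)
})

test_that("breaths shorter than min_period are excluded", {
  fs <- 32
  x <- cosine_epoch(fs, period = 0.4)       # 0.4 s < default 0.5 s
  seg <- segment_breaths(x, fs, min_period = 0.5)
  expect_equal(nrow(seg$breaths), 0)
  seg2 <- segment_breaths(x, fs, min_period = 0.3)
  expect_gt(nrow(seg2$breaths), 50)
})

test_that("rate_features match hand computation on a known segmentation", {
  fs <- 16
  x <- cosine_epoch(fs, period = 1.25)
  seg <- segment_breaths(x, fs)
  rf <- rate_features(seg)
  f <- 1 / seg$breaths$period
  expect_equal(rf[["bf_var"]], var(f))
  expect_equal(rf[["bf_median"]], median(f))
  expect_equal(rf[["log_bpm"]], log(60 / mean(seg$breaths$period)))
  expect_equal(rf[["bf_rel_change"]],
               mean(abs(diff(f)) / diff(seg$breaths$tp)))
  # under 3 breaths -> all NA
  seg$breaths <- seg$breaths[1:2, ]
  expect_true(all(is.na(rate_features(seg))))
})

test_that("breath_correlation is ~1 for identical breath shapes", {
  fs <- 16
  x <- cosine_epoch(fs, period = 1.25)
  seg <- segment_breaths(x, fs)
  bc <- breath_correlation(x, fs, seg)
  expect_gt(bc[["bb_corr_mean"]], 0.99)
  expect_gt(bc[["bb_corr_min"]], 0.98)
  expect_lte(bc[["bb_corr_max"]], 1 + 1e-12)
})

test_that("breath_correlation drops for irregular breathing", {
  cfg <- sim_config(n_epochs = 1, seed = 62)
  hyp <- structure("CTW", class = "hypnogram", epoch_s = 30)  # high jitter
  y <- generate_respiration(hyp, cfg, seed = 63)
  seg <- segment_breaths(y, cfg$fs_resp)
  bc <- breath_correlation(y, cfg$fs_resp, seg)
  x <- cosine_epoch(cfg$fs_resp, period = 1.25)
  bc0 <- breath_correlation(x, cfg$fs_resp, segment_breaths(x, cfg$fs_resp))
  expect_lt(bc[["bb_corr_mean"]], bc0[["bb_corr_mean"]])
})

test_that("resp_spectral_features put a sinusoid's power in the right band", {
  fs <- 16
  # 0.8 Hz breathing -> HF band (0.15-0.5 Hz excluded; 0.8 is outside all
  # bands) - use 0.4 Hz so it lands in HF
  x <- cosine_epoch(fs, period = 2.5)        # 0.4 Hz
  sp <- resp_spectral_features(x, fs)
  expect_gt(sp[["resp_norm_hf"]], 0.9)
  expect_lt(sp[["resp_norm_vlf"]] + sp[["resp_norm_lf"]], 0.1)
  expect_equal(sp[["resp_dom_freq"]], 0.4, tolerance = fs / 256 + 1e-9)
  # normalized powers sum to ~1
  expect_equal(sp[["resp_norm_vlf"]] + sp[["resp_norm_lf"]] +
                 sp[["resp_norm_hf"]], 1, tolerance = 0.05)
})

test_that("amplitude_features match hand computation", {
  fs <- 16
  x <- cosine_epoch(fs, period = 1.5, amp = 2)
  seg <- segment_breaths(x, fs)
  af <- amplitude_features(seg, epoch_sd = sd(x))
  expect_equal(af[["std_median_peak"]], median(seg$peaks$amp) / sd(x))
  expect_equal(af[["std_median_trough"]], median(seg$troughs$amp) / sd(x))
  k <- min(nrow(seg$peaks), nrow(seg$troughs))
  expect_equal(af[["median_peak_trough_diff"]],
               median(seg$peaks$amp[1:k] - seg$troughs$amp[1:k]))
  # symmetric oscillation: log peak/|trough| ratio ~ 0
  expect_equal(af[["log_pt_ratio_median"]], 0, tolerance = 0.05)
})

test_that("flow_volume_features are exact on a triangular wave", {
  fs <- 16
  # triangle: 1-s rise 0->1, 1-s fall 1->0, repeated
  half <- fs
  one <- c(seq(0, 1, length.out = half + 1)[-1],
           seq(1, 0, length.out = half + 1)[-1])
  x <- rep(one, 15)
  seg <- segment_breaths(x, fs)
  fv <- flow_volume_features(x, fs, seg)
  # symmetric limbs: inhale/exhale time and flow ratios = 1
  expect_equal(fv[["ie_time_ratio"]], 1, tolerance = 1e-9)
  expect_equal(fv[["ie_flow_ratio"]], 1, tolerance = 1e-9)
  expect_equal(fv[["ie_time_ratio_breath"]], 1, tolerance = 1e-9)
  # inhale limb volume: integral of a unit triangle limb over 1 s = 1/2
  expect_equal(fv[["vol_inhale_median"]], 0.5, tolerance = 0.05)
  expect_equal(fv[["flow_inhale_median"]], 1, tolerance = 1e-9)
  expect_equal(fv[["amp_ratio_mean"]], 1, tolerance = 1e-9)
  expect_equal(fv[["amp_ratio_sd"]], 0, tolerance = 1e-9)
})

test_that("resp_regularity is low for periodic and higher for random input", {
  fs <- 16
  x <- cosine_epoch(fs, period = 4)
  set.seed(64)
  y <- rnorm(length(x))
  expect_lt(resp_regularity(x, fs), resp_regularity(y, fs))
  expect_equal(resp_regularity(rep(2, 480), fs), 0)
})

test_that("extract_respiratory returns 41 named features in registry order", {
  cfg <- sim_config(n_epochs = 1, seed = 65)
  rec <- simulate_recording(cfg)
  ep <- epochize(preprocess_recording(rec))[[1]]
  v <- extract_respiratory(ep)
  expect_length(v, 41)
  expect_identical(names(v), neosleep:::resp_feature_names)
  expect_true(all(is.na(v) | is.finite(v)))
  core <- c("bf_median", "log_bpm", "bb_corr_mean", "resp_norm_hf",
            "vol_cycle_median", "ie_time_ratio", "resp_sampen")
  expect_false(anyNA(v[core]))
})

test_that("extract_respiratory degrades gracefully on a flat epoch", {
  ep <- list(resp = rep(0, 480), fs_resp = 16)
  v <- extract_respiratory(ep)
  expect_length(v, 41)
  expect_true(is.na(v[["bf_median"]]))
  expect_equal(v[["resp_sampen"]], 0)
})
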