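cfg_small <- function(...) sim_config(n_epochs = 40, seed = 5, ...)

test_that("bout_transition_matrix has the requested stationary mix and bouts", {
  f <- c(AS = 0.72, QS = 0.12, CTW = 0.16)
  L <- c(AS = 20, QS = 10, CTW = 5)
  P <- neosleep:::bout_transition_matrix(f, L)
  expect_equal(rowSums(P), c(AS = 1, QS = 1, CTW = 1), tolerance = 1e-10)
  expect_true(all(P >= 0))
  # stationarity: f P = f
  expect_equal(as.numeric(f %*% P), as.numeric(f), tolerance = 1e-8)
  # geometric bout means: E[L] = 1 / (1 - P[s, s])
  expect_equal(1 / (1 - diag(P)), L, tolerance = 1e-8)
})

test_that("generate_hypnogram is deterministic in the seed and well-formed", {
  cfg <- sim_config(n_epochs = 200, seed = 3)
  h1 <- generate_hypnogram(cfg)
  h2 <- generate_hypnogram(cfg)
  expect_identical(as.character(h1), as.character(h2))
  expect_length(h1, 200)
  expect_true(all(h1 %in% c("AS", "QS", "CTW")))
  h3 <- generate_hypnogram(cfg, seed = 4)
  expect_false(identical(as.character(h1), as.character(h3)))
})

test_that("hypnogram state fractions concentrate around the targets", {
  cfg <- sim_config(n_epochs = 2000)
  fr <- vapply(1:30, function(s)
    mean(generate_hypnogram(cfg, seed = s) == "AS"), 0.0)
  # the mean over seeds must sit near the 0.72 target; single recordings are
  # strongly autocorrelated (mean AS bout = 20 epochs) so their spread is wide
  expect_lt(abs(mean(fr) - 0.72), 0.03)
  qs <- vapply(1:30, function(s)
    mean(generate_hypnogram(cfg, seed = s) == "QS"), 0.0)
  expect_lt(abs(mean(qs) - 0.12), 0.03)
})

test_that("generate_rpeaks produces plausible, state-dependent RR intervals", {
  cfg <- sim_config(n_epochs = 20, seed = 2)
  hyp_as <- structure(rep("AS", 20), class = "hypnogram", epoch_s = 30)
  hyp_qs <- structure(rep("QS", 20), class = "hypnogram", epoch_s = 30)
  r_as <- generate_rpeaks(hyp_as, cfg, seed = 10)
  r_qs <- generate_rpeaks(hyp_qs, cfg, seed = 10)
  expect_true(all(diff(r_as) > 0))
  expect_true(all(r_as >= 0 & r_as < 600))
  # mean RR tracks the configured state means (decelerations inflate slightly)
  expect_lt(abs(mean(diff(r_as)) * 1000 - 380), 25)
  expect_lt(abs(mean(diff(r_qs)) * 1000 - 430), 25)
  # QS is the low-variability state
  expect_lt(sd(diff(r_qs)), sd(diff(r_as)))
})

test_that("generate_respiration has the right length and breath rate", {
  cfg <- cfg_small()
  hyp <- structure(rep("QS", 40), class = "hypnogram", epoch_s = 30)
  y <- generate_respiration(hyp, cfg, seed = 8)
  expect_length(y, 40 * 30 * cfg$fs_resp)
  seg <- segment_breaths(y[1:(30 * cfg$fs_resp)], cfg$fs_resp)
  # QS: 48 breaths/min -> ~24 breaths in 30 s
  expect_gt(nrow(seg$breaths), 15)
  expect_lt(nrow(seg$breaths), 32)
})

test_that("generate_motion separates CTW from QS in burst activity", {
  cfg <- cfg_small()
  hyp_ctw <- structure(rep("CTW", 40), class = "hypnogram", epoch_s = 30)
  hyp_qs <- structure(rep("QS", 40), class = "hypnogram", epoch_s = 30)
  m_ctw <- generate_motion(hyp_ctw, cfg, seed = 30)
  m_qs <- generate_motion(hyp_qs, cfg, seed = 30)
  expect_true(all(m_ctw >= 0))
  expect_length(m_ctw, 40 * 30 * cfg$fs_motion)
  expect_gt(sum(m_ctw), 5 * sum(m_qs))
})

test_that("generate_ecg_waveform places QRS peaks at the R times", {
  cfg <- sim_config(seed = 1, ecg_noise_sd = 0.02)
  rpk <- seq(0.4, 29.5, by = 0.4)
  y <- generate_ecg_waveform(rpk, cfg, 30, seed = 40)
  expect_length(y, 30 * cfg$fs_ecg)
  # the sample-level argmax near each R time is within 1 sample of it
  for (rt in rpk[1:10]) {
    i0 <- round((rt - 0.05) * cfg$fs_ecg):round((rt + 0.05) * cfg$fs_ecg)
    pk <- i0[which.max(y[i0 + 1])]
    expect_lt(abs(pk / cfg$fs_ecg - rt), 2 / cfg$fs_ecg)
  }
  expect_error(generate_ecg_waveform(c(1, 1), cfg, 30))
})

test_that("simulate_recording is reproducible and internally consistent", {
  cfg <- cfg_small()
  rec1 <- simulate_recording(cfg, subject_id = "A")
  rec2 <- simulate_recording(cfg, subject_id = "A")
  expect_identical(rec1$rpeaks, rec2$rpeaks)
  expect_identical(rec1$resp, rec2$resp)
  expect_s3_class(rec1, "sleep_recording")
  expect_equal(nrow(rec1$annotations), 40)
  expect_equal(length(rec1$resp) / cfg$fs_resp,
               length(rec1$motion) / cfg$fs_motion)
  expect_equal(length(rec1$ecg) / cfg$fs_ecg, 40 * 30)
  expect_identical(rec1$annotations$epoch_index, 0:39)
})

test_that("unknown_frac relabels the requested share of epochs", {
  cfg <- sim_config(n_epochs = 100, seed = 6, unknown_frac = 0.2,
                    include_ecg = FALSE)
  rec <- simulate_recording(cfg)
  expect_equal(sum(rec$annotations$label == "Unknown"), 20)
})

test_that("simulate_cohort yields distinct deterministic subjects", {
  cfg <- cfg_small(include_ecg = FALSE)
  coh1 <- simulate_cohort(3, cfg, seed = 9)
  coh2 <- simulate_cohort(3, cfg, seed = 9)
  expect_length(coh1, 3)
  expect_identical(vapply(coh1, `[[`, "", "subject_id"), c("S1", "S2", "S3"))
  expect_identical(coh1[[2]]$rpeaks, coh2[[2]]$rpeaks)
  expect_false(identical(coh1[[1]]$rpeaks, coh1[[2]]$rpeaks))
})

test_that("simulator rejects invalid configurations", {
  expect_error(sim_config(fractions = c(AS = 0.5, QS = 0.3, CTW = 0.3)),
               "sum to 1")
  expect_error(sim_config(n_epochs = 0), "at least 1")
  expect_error(state_params(mean_rr = -5, sd_rr = 1, breath_rate = 50,
                            breath_rate_jitter = 0.1, breath_amp = 1,
                            breath_amp_cv = 0.1, motion_burst_rate = 1,
                            motion_burst_amp = 1))
  # fractions/bout-lengths demanding more exit flow than available
  expect_error(neosleep:::bout_transition_matrix(
    c(AS = 0.98, QS = 0.01, CTW = 0.01), c(AS = 1, QS = 50, CTW = 50)))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(77)
  a <- rnorm(1)
  set.seed(77)
  invisible(simulate_recording(cfg_small()))
  b <- rnorm(1)
  expect_identical(a, b)
})
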