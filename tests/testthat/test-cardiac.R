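sim_epoch <- function(state = "QS", seed = 51) state_epoch(state, seed)

test_that("rr_from_rpeaks computes intervals and validity flags", {
  r <- c(0.5, 1.0, 1.4, 2.5, 2.8)
  rrs <- rr_from_rpeaks(r, range = c(200, 750))
  expect_equal(rrs$rr, c(500, 400, 1100, 300))
  expect_identical(rrs$valid, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(rrs$t, r[-1])
  expect_length(rr_from_rpeaks(numeric(0))$rr, 0)
  expect_length(rr_from_rpeaks(1.5)$rr, 0)
})

test_that("time-domain HRV statistics match direct computation", {
  ep <- sim_epoch("AS", seed = 52)
  v <- extract_cardiac(ep)
  rr <- diff(ep$rpeaks) * 1000
  rr <- rr[rr >= 200 & rr <= 750]
  expect_equal(v[["beats_per_epoch"]], length(ep$rpeaks))
  expect_equal(v[["rr_mean"]], mean(rr))
  expect_equal(v[["rr_sdnn"]], sd(rr))
  expect_equal(v[["rr_cv"]], sd(rr) / mean(rr))
  expect_equal(v[["rr_iqr"]], IQR(rr))
  d <- diff(rr)
  expect_equal(v[["rmssd"]], sqrt(mean(d^2)))
  expect_equal(v[["pnn20"]], mean(abs(d) > 20))
  expect_equal(v[["hr_mean"]], mean(60000 / rr))
  expect_equal(v[["rr_sampen"]],
               oracle_sampen(rr, 2, 0.2 * sd(rr)), tolerance = 1e-12)
})

test_that("hrv_band_powers integrates a synthetic modulated tachogram", {
  # RR sequence with a pure 0.1 Hz (LF) oscillation
  t <- cumsum(rep(0.4, 300))
  rr <- 400 + 20 * sin(2 * pi * 0.1 * t)
  rrs <- list(rr = rr, valid = rep(TRUE, length(rr)), t = t)
  bp <- hrv_band_powers(rrs)
  expect_gt(bp[["lf"]], 10 * bp[["hf"]])
  expect_gt(bp[["lf"]], 10 * bp[["vlf"]])
  # total power ~ variance of the modulation (20^2 / 2)
  expect_equal(sum(bp), 200, tolerance = 60)
})

test_that("hrv_band_powers returns NA for sparse beat trains", {
  rrs <- rr_from_rpeaks(c(0.5, 1.0, 1.5, 2.0))
  expect_true(all(is.na(hrv_band_powers(rrs))))
})

test_that("line_length_features match direct sums", {
  set.seed(53)
  x <- rnorm(500 * 3)
  got <- line_length_features(x, 500)
  expect_equal(got[1], sum(abs(diff(x))))
  subs <- vapply(1:3, function(i)
    sum(abs(diff(x[((i - 1) * 500 + 1):(i * 500)]))), 0.0)
  expect_equal(got[2], mean(subs))
  expect_equal(got[3], sd(subs))
})

test_that("hr_decelerations detects a planted deceleration run", {
  rr <- rep(400, 60)
  rr[30:33] <- 400 * 1.25            # 4-beat run 25% above baseline
  rrs <- list(rr = rr, valid = rep(TRUE, 60), t = cumsum(rr) / 1000)
  got <- hr_decelerations(rrs, theta = 0.1, window = 15, min_run = 2)
  expect_equal(got[1], 4 / 60)
  expect_equal(got[2], 0.25, tolerance = 1e-9)
  # no decelerations -> exact zeros
  rrs0 <- list(rr = rep(400, 60), valid = rep(TRUE, 60),
               t = cumsum(rep(0.4, 60)))
  expect_equal(hr_decelerations(rrs0), c(0, 0))
  # too few beats -> NA
  expect_true(all(is.na(hr_decelerations(rr_from_rpeaks(c(0.4, 0.8, 1.2))))))
})

test_that("single-beat runs are ignored below min_run", {
  rr <- rep(400, 40)
  rr[20] <- 520
  rrs <- list(rr = rr, valid = rep(TRUE, 40), t = cumsum(rr) / 1000)
  expect_equal(hr_decelerations(rrs, min_run = 2)[1], 0)
  expect_equal(hr_decelerations(rrs, min_run = 1)[1], 1 / 40)
})

test_that("extract_cardiac returns 34 named finite-or-NA features", {
  ep <- sim_epoch("QS", seed = 54)
  v <- extract_cardiac(ep)
  expect_length(v, 34)
  expect_identical(names(v), neosleep:::cardiac_feature_names)
  expect_true(all(is.na(v) | is.finite(v)))
  # QS epoch with ECG present: the core features must be defined
  core <- c("rr_mean", "rr_sdnn", "hrv_lf", "ecg_line_length", "ecg_lz",
            "decel_pct")
  expect_false(anyNA(v[core]))
})

test_that("extract_cardiac handles an epoch without beats or ECG", {
  ep <- sim_epoch("QS", seed = 55)
  ep$rpeaks <- numeric(0)
  ep$ecg <- NULL
  v <- extract_cardiac(ep)
  expect_equal(v[["beats_per_epoch"]], 0)
  expect_true(all(is.na(v[setdiff(names(v), "beats_per_epoch")])))
})

test_that("QS epochs have lower RR variability than AS epochs", {
  vas <- extract_cardiac(sim_epoch("AS", seed = 56))
  vqs <- extract_cardiac(sim_epoch("QS", seed = 56))
  expect_lt(vqs[["rr_sdnn"]], vas[["rr_sdnn"]])
  expect_gt(vqs[["rr_mean"]], vas[["rr_mean"]])
})
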