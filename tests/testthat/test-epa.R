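# Signal processing and feature extraction: windowing, cleaning,
# decomposition, SCR features, channel features, imputation.

test_that("window extraction is causal, half-open and coverage-aware", {
  st <- sw <- list(channel = "EDA", start = 1000, rate = 4,
                   samples = seq_len(4 * 1200))   # 1200 s of samples
  win <- extract_window(st, beep_time = 1000 + 900, window = 600)
  expect_equal(length(win$samples), 2400)
  expect_equal(win$coverage, 1)
  # causal: last sample strictly before the beep
  expect_equal(max(win$samples), (900 - 0.25) * 4 + 1)
  # recording starts exactly 300 s before the beep -> coverage 0.5, accepted
  st2 <- list(channel = "EDA", start = 1000, rate = 4,
              samples = seq_len(4 * 300))
  win2 <- extract_window(st2, beep_time = 1300, window = 600)
  expect_equal(win2$coverage, 0.5)
  expect_false(win2$missing)
  # beep entirely outside the recording -> missing
  win3 <- extract_window(st2, beep_time = 5000, window = 600)
  expect_true(win3$missing)
})

test_that("a beep during a recording gap is flagged missing", {
  co <- generate_cohort(small_config(n = 1, days = 1, beeps = 2, seed = 21))
  st <- simulate_physio_day(co, "P001", 1, 1, channels = "eda")
  # a beep scheduled before the session started has no coverage
  early <- st$eda$start - 3600
  expect_true(extract_window(st$eda, early, 600)$missing)
})

test_that("cleaning is near-identity on clean signals and removes artifacts", {
  cfg <- eda_config()
  x <- simulate_eda_segment(600, 4, event_times = c(120, 400),
                            event_amps = 0.5, tonic = 1.2)
  cl <- clean_eda(x, 4, cfg)
  expect_true(cl$ok)
  # near-identity: deviation bounded by the filter ripple on SCR peaks
  expect_lt(max(abs(cl$signal - x)), 0.05)
  # single 1-sample +1 uS spike is removed almost completely
  xs <- simulate_eda_segment(600, 4, tonic = 1.2, spike_times = 300,
                             spike_amps = 1, spike_width = 1)
  cls <- clean_eda(xs, 4, cfg)
  i <- 300 * 4 + 1
  expect_lt(abs(cls$signal[i] - 1.2), 0.05)
  # wider (2-sample) artifact bursts are removed by the delta-denoiser
  xw <- simulate_eda_segment(600, 4, tonic = 1.2, spike_times = 300,
                             spike_amps = 0.6, spike_width = 2)
  clw <- clean_eda(xw, 4, cfg)
  expect_lt(max(abs(clw$signal - 1.2)), 0.05)
  # constant signal below the 0.01 uS floor -> missing
  low <- clean_eda(rep(0.005, 2400), 4, cfg)
  expect_false(low$ok)
  expect_equal(low$reason, "below_quality_floor")
})

test_that("no sample-to-sample artifact change beyond delta survives cleaning", {
  cfg <- eda_config()
  set.seed(31)
  x <- simulate_eda_segment(600, 4, tonic = 1.2, noise_sd = 0.002,
                            spike_times = c(100, 350, 520),
                            spike_amps = c(0.3, 0.8, 0.15), spike_width = 2)
  cl <- clean_eda(x, 4, cfg)
  # after cleaning, remaining jumps are far below the artifact amplitudes
  expect_lt(max(abs(diff(cl$signal))), 0.05)
})

test_that("decomposition satisfies its reconstruction and linearity oracles", {
  cfg <- eda_config()
  # pure tonic ramp: phasic stays ~0
  ramp <- seq(1, 2, length.out = 2400)
  dec <- decompose_eda(ramp, 4, cfg)
  expect_lt(max(abs(dec$phasic)), 0.01)
  expect_equal(dec$tonic, ramp, tolerance = 0.01)
  # single unit pulse at t = 100 s: dominant driver peak at 100 s
  x1 <- simulate_eda_segment(600, 4, event_times = 100, event_amps = 1,
                             tonic = 0.5)
  d1 <- decompose_eda(x1, 4, cfg)
  expect_equal((which.max(d1$driver) - 1) / 4, 100, tolerance = 0.5)
  # amplitude linearity of the recovered driver
  x2 <- simulate_eda_segment(600, 4, event_times = 100, event_amps = 2,
                             tonic = 0.5)
  d2 <- decompose_eda(x2, 4, cfg)
  expect_equal(max(d2$driver) / max(d1$driver), 2, tolerance = 0.05)
  # reconstruction: driver reconvolved with the kernel reproduces the signal
  x <- simulate_eda_segment(600, 4, event_times = c(100, 300, 500),
                            event_amps = 0.5, tonic = 1.2)
  d <- decompose_eda(x, 4, cfg)
  n <- length(x)
  nf <- stats::nextn(n + length(d$kernel), 2)
  rec <- Re(stats::fft(stats::fft(c(d$driver, rep(0, nf - n))) *
                         stats::fft(c(d$kernel, rep(0, nf - length(d$kernel)))),
                       inverse = TRUE))[1:n] / nf + d$baseline
  expect_lt(sqrt(mean((rec - x)^2)) / sd(x), 0.05)
  # components always sum back to the signal
  expect_equal(d$tonic + d$phasic, x, tolerance = 1e-9)
})

test_that("SCR features recover injected events and satisfy additivity", {
  cfg <- eda_config()
  # 3 injected SCRs of 0.5 uS, no noise
  x <- simulate_eda_segment(600, 4, event_times = c(100, 300, 500),
                            event_amps = 0.5, tonic = 1.2)
  f <- scr_features(decompose_eda(x, 4, cfg), 4, cfg)
  expect_equal(f$scr_count, 3)
  expect_equal(f$scr_magnitude, 0.5, tolerance = 0.05)
  expect_equal(f$tonic_mean, 1.2, tolerance = 0.02)
  # zero phasic
  f0 <- scr_features(decompose_eda(rep(1.2, 2400), 4, cfg), 4, cfg)
  expect_equal(f0$scr_count, 0)
  expect_equal(f0$scr_magnitude, 0)
  expect_equal(f0$scr_auc, 0, tolerance = 1e-6)
  expect_equal(f0$tonic_mean, 1.2)
  # AUC additivity: disjoint event sets sum (numeric integration oracle)
  xa <- simulate_eda_segment(600, 4, event_times = c(50, 150),
                             event_amps = 0.4, tonic = 1)
  xb <- simulate_eda_segment(600, 4, event_times = c(350, 450),
                             event_amps = 0.6, tonic = 1)
  xab <- simulate_eda_segment(600, 4,
                              event_times = c(50, 150, 350, 450),
                              event_amps = c(0.4, 0.4, 0.6, 0.6), tonic = 1)
  auc <- function(x) scr_features(decompose_eda(x, 4, cfg), 4, cfg)$scr_auc
  expect_equal(auc(xa) + auc(xb), auc(xab), tolerance = 0.01 * auc(xab))
})

test_that("end-to-end SCR recovery across K = 0..10 injected events", {
  cfg <- eda_config()
  res <- NULL
  for (k in 0:10) {
    et <- if (k) seq(20, 560, length.out = k) else numeric(0)
    x <- simulate_eda_segment(600, 4, event_times = et, event_amps = 0.45,
                              tonic = 1.2)
    cl <- clean_eda(x, 4, cfg)
    f <- scr_features(decompose_eda(cl$signal, 4, cfg), 4, cfg)
    res <- rbind(res, c(k, f$scr_count, f$scr_magnitude))
  }
  expect_gte(mean(res[, 1] == res[, 2]), 0.9)
  nz <- res[res[, 1] > 0, ]
  expect_lt(abs(mean(nz[, 3]) / 0.45 - 1), 0.1)
})

test_that("channel features match closed forms", {
  expect_equal(hr_features(rep(60, 600)),
               list(hr_mean = 60, hr_min = 60, hr_max = 60))
  expect_true(is.na(hr_features(numeric(0))$hr_mean))
  # temp slope: 33 + 0.1 C/min ramp
  tmin <- (0:2399) / 4 / 60
  tf <- temp_features(33 + 0.1 * tmin, 4)
  expect_equal(tf$temp_slope, 0.1, tolerance = 1e-6)
  expect_true(tf$temp_ok)
  # dead sensor: constant 0 C flagged invalid
  expect_false(temp_features(rep(0, 2400), 4)$temp_ok)
  # stationary wrist: zero movement
  expect_equal(acc_features(matrix(rep(c(0, 0, 1), each = 100), 100, 3))$acc_rmsd, 0)
  hrf <- hr_features(c(55, 60, 70))
  expect_true(hrf$hr_min <= hrf$hr_mean && hrf$hr_mean <= hrf$hr_max)
})

test_that("population imputation draws from the donor distribution", {
  set.seed(1)
  feats <- tibble::tibble(
    participant_id = rep(sprintf("P%02d", 1:10), each = 20),
    beep_id = sprintf("b%d", 1:200),
    temp_mean = rnorm(200, 33, 0.5), temp_slope = rnorm(200, 0, 0.02))
  feats$temp_mean[feats$participant_id %in% c("P01", "P02")] <- NA
  feats$temp_slope[feats$participant_id %in% c("P01", "P02")] <- NA
  out <- impute_population(feats, seed = 7)
  expect_false(any(is.na(out$temp_mean)))
  expect_true(all(out$imputed_temp_mean[out$participant_id == "P01"]))
  expect_false(any(out$imputed_temp_mean[out$participant_id == "P03"]))
  # many draws concentrate on the donor mean
  donors <- feats$temp_mean[!is.na(feats$temp_mean)]
  expect_equal(mean(out$temp_mean[out$imputed_temp_mean]), mean(donors),
               tolerance = 3 * sd(donors) / sqrt(40))
  # zero-variance donors -> all imputations equal the mean
  fz <- feats
  fz$temp_mean[!is.na(fz$temp_mean)] <- 33
  oz <- impute_population(fz, "temp_mean", seed = 7)
  expect_true(all(oz$temp_mean == 33))
  # no donors -> hard error
  fe <- feats
  fe$temp_mean <- NA_real_
  expect_error(impute_population(fe, "temp_mean"), "donors")
})

test_that("feature extraction is idempotent and window-mode matches full-day", {
  co <- small_cohort()
  f1 <- extract_epa_features(co)
  f2 <- extract_epa_features(co)
  expect_identical(f1, f2)
  ws <- stressweek:::simulate_window_streams(co, "P001", 1, 2)
  st <- simulate_physio_day(co, "P001", 1, 2)
  for (k in seq_len(nrow(ws$tr))) {
    full <- extract_window(st$eda, ws$tr$scheduled_time[k], 600)$samples
    expect_equal(ws$eda[[k]]$samples, full, tolerance = 1e-6)
  }
})
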