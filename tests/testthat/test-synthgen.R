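# Synthetic cohort generator: schedules, determinism, compliance,
# item emission, generative effect oracle, sensor dialect round-trip.

test_that("schedule has the full beep grid and week-order balance", {
  co <- small_cohort()
  cfg <- co$config
  expect_equal(nrow(co$ema),
               cfg$n_participants * 2 * cfg$days_per_week * cfg$beeps_per_day)
  # minimal schedule: one beep per arm
  co1 <- generate_cohort(small_config(n = 1, days = 1, beeps = 1))
  expect_equal(nrow(co1$ema), 2)
  expect_setequal(co1$ema$week_type, c("stress", "control"))
  # default design at scale: 84 beeps each; stress-first fraction near 27/83
  co2 <- generate_cohort(study_config(n_participants = 83, seed = 202,
                                      n_faulty_temp = 0))
  expect_equal(nrow(co2$ema), 83 * 84)
  p <- mean(co2$participants$stress_week_first)
  expect_lt(abs(p - 27 / 83), 3 * sqrt(0.325 * 0.675 / 83))
})

test_that("identical config and seed give identical cohorts and streams", {
  a <- generate_cohort(small_config(seed = 5))
  b <- generate_cohort(small_config(seed = 5))
  expect_identical(a$ema, b$ema)
  expect_identical(a$truth, b$truth)
  sa <- simulate_physio_day(a, "P001", 1, 1)
  sb <- simulate_physio_day(b, "P001", 1, 1)
  expect_identical(sa$eda$samples, sb$eda$samples)
  expect_identical(sa$acc$samples, sb$acc$samples)
  c2 <- generate_cohort(small_config(seed = 6))
  expect_false(identical(a$ema$na_1, c2$ema$na_1))
})

test_that("realized compliance and joint availability match the configuration", {
  co <- generate_cohort(study_config(n_participants = 60, seed = 77,
                                     n_faulty_temp = 0))
  rec <- filter_compliance(co$ema, co$config$beep_window)
  expect_lt(abs(mean(rec$compliance_flag) - 0.85), 0.02)
  joint <- mean(rec$compliance_flag & co$truth$epa_contact[
    match(rec$beep_id, co$truth$beep_id)])
  expect_lt(abs(joint - 0.85 * 0.905), 0.02)
})

test_that("null generator scores at the neutral midpoint; reversal symmetric", {
  eff <- null_effects()
  eff$random_effect_sds$intercept <- lapply(
    eff$random_effect_sds$intercept, function(x) 1e-12)
  eff$random_effect_sds$slope <- lapply(
    eff$random_effect_sds$slope, function(x) 1e-12)
  eff$item_noise_sd <- 1e-12
  co <- generate_cohort(study_config(n_participants = 6, seed = 3,
                                     n_faulty_temp = 0), eff)
  rec <- filter_compliance(co$ema, co$config$beep_window)
  sc <- score_scales(rec, co$scale_map)
  ok <- sc$compliance_flag
  # residual latent noise remains (budget solves to ~unit variance), but the
  # scored means sit at the 0.5 midpoint
  for (s in ema_scales())
    expect_lt(abs(mean(sc[[s]][ok]) - 0.5), 0.05)
  # reversal symmetry: a latent at the item maximum emits reversed items at 1
  items <- simulate_ema_response(
    stats::setNames(as.list(rep(10, 6)), ema_scales()),
    item_noise_sd = 1e-12)
  expect_equal(unname(items["pa_4"]), 1L)
  expect_equal(unname(items["pa_1"]), 7L)
  expect_equal(unname(items["na_5"]), 1L)
})

test_that("Monte-Carlo oracle: scored week effect equals the configured truth", {
  # one participant-free contrast: many beeps, no random effects, so the
  # generative equation itself is the oracle
  eff <- default_effects()
  eff$random_effect_sds$intercept <- lapply(
    eff$random_effect_sds$intercept, function(x) 1e-12)
  eff$random_effect_sds$slope <- lapply(
    eff$random_effect_sds$slope, function(x) 1e-12)
  co <- generate_cohort(study_config(n_participants = 6, days_per_week = 25,
                                     beeps_per_day = 6, seed = 88,
                                     ema_compliance = 1, n_faulty_temp = 0),
                        eff)   # 6 x 2 x 25 x 6 = 1800 beeps per week type
  sc <- score_scales(co$ema, co$scale_map)
  z <- (sc$event_stress - mean(sc$event_stress)) / sd(sc$event_stress)
  d <- mean(z[sc$week_type == "stress"]) - mean(z[sc$week_type == "control"])
  expect_equal(d, 0.30, tolerance = 0.06)   # MC error ~ 2/sqrt(1800)
})

test_that("sensor export dialect round-trips through write and read", {
  co <- generate_cohort(small_config(n = 2, days = 1, beeps = 2, seed = 9))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  sess <- file.path(dir, "P001", "w1_d1")
  expect_true(all(file.exists(file.path(
    sess, c("EDA.csv", "HR.csv", "TEMP.csv", "ACC.csv", "IBI.csv")))))
  st <- simulate_physio_day(co, "P001", 1, 1)
  rd <- read_e4_session(sess)
  expect_equal(rd$eda$start, st$eda$start)
  expect_equal(rd$eda$rate, 4)
  expect_equal(rd$eda$samples, st$eda$samples, tolerance = 1e-6)
  expect_equal(dim(rd$acc$samples), dim(st$acc$samples))
  expect_equal(rd$ibi$samples$interval, st$ibi$samples$interval,
               tolerance = 1e-6)
  ema2 <- read_ema_table(file.path(dir, "ema_long.csv"))
  expect_equal(nrow(ema2), nrow(co$ema))
})

test_that("interbeat intervals cover the configured fraction of each window", {
  co <- generate_cohort(small_config(n = 1, days = 2, beeps = 3, seed = 15))
  covs <- c()
  for (d in 1:2) {
    st <- simulate_physio_day(co, "P001", 1, d, channels = "ibi")
    tr <- co$truth[co$truth$participant_id == "P001" &
                     co$truth$week_index == 1 & co$truth$day_index == d, ]
    for (bt in tr$scheduled_time) {
      off <- bt - st$ibi$start
      seg <- st$ibi$samples[st$ibi$samples$offset > off - 600 &
                              st$ibi$samples$offset <= off, ]
      covs <- c(covs, sum(seg$interval) / 600)
    }
  }
  expect_equal(mean(covs), 0.27, tolerance = 0.05)
})

test_that("ground-truth SCR bookkeeping matches the emitted event lists", {
  co <- small_cohort()
  expect_equal(lengths(co$truth$event_offsets), co$truth$scr_count_true)
  expect_true(all(unlist(co$truth$event_amps) > 0))
  expect_true(all(unlist(co$truth$event_offsets) >= 0 &
                    unlist(co$truth$event_offsets) <= 600))
})
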