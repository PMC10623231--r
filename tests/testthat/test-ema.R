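# EMA scoring: compliance filtering, reverse-scoring, rescaling,
# person-centering, median-split incongruence.

beep_tbl <- function(completed_offset) {
  tibble::tibble(participant_id = "P1",
                 beep_id = sprintf("b%d", seq_along(completed_offset)),
                 scheduled_time = 1000,
                 completed_time = 1000 + completed_offset)
}

test_that("compliance window is a closed one-hour boundary", {
  rec <- filter_compliance(beep_tbl(c(59 * 60, 60 * 60, 61 * 60, NA, -5)))
  expect_equal(rec$compliance_flag, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_error(filter_compliance(beep_tbl(0), window = -1),
               class = "stressweek_config_error")
})

test_that("scale scoring inverts reversed items, sums and rescales", {
  map <- list(pa = list(items = paste0("pa_", 1:4), reversed = "pa_4"),
              na = list(items = paste0("na_", 1:5), reversed = character(0)))
  rec <- tibble::tibble(participant_id = "P1", beep_id = c("b1", "b2", "b3"),
                        pa_1 = c(7, 4, 1), pa_2 = c(7, 4, NA),
                        pa_3 = c(7, 4, 2),
                        pa_4 = c(1, 6, 3),  # emitted inverted: 1 scores as 7
                        na_1 = 1, na_2 = 1, na_3 = 1, na_4 = 1, na_5 = 1)
  sc <- score_scales(rec, map)
  # all four PA items at scored maximum -> rescaled exactly 1
  expect_equal(sc$pa[1], 1.0)
  expect_equal(sc$pa_raw[1], 28)
  # hand computation of the inversion rule: 4 + 4 + 4 + (8 - 6) = 14
  expect_equal(sc$pa_raw[2], 14)
  expect_equal(sc$pa[2], (14 - 4) / 24)
  # any missing item makes the scale missing (no prorating)
  expect_true(is.na(sc$pa[3]))
  # NA minimum: raw sum 5, rescaled 0
  expect_equal(sc$na_raw[1], 5)
  expect_equal(sc$na[1], 0)
  expect_error(score_scales(rec[, -2], default_scale_map()), "item")
})

test_that("scoring is invariant to item order and inversion is an involution", {
  co <- small_cohort()
  rec <- filter_compliance(co$ema, co$config$beep_window)
  sc1 <- score_scales(rec, co$scale_map)
  map2 <- co$scale_map
  for (s in names(map2)) map2[[s]]$items <- rev(map2[[s]]$items)
  sc2 <- score_scales(rec, map2)
  expect_equal(sc1$na, sc2$na)
  expect_equal(sc1$event_stress, sc2$event_stress)
  # involution: inverting twice restores the raw items
  v <- rec$pa_4[!is.na(rec$pa_4)]
  expect_equal(8 - (8 - v), v)
})

test_that("person-centering removes participant means and drops sparse cases", {
  sc <- tibble::tibble(
    participant_id = rep(c("A", "B"), c(3, 1)),
    beep_id = sprintf("b%d", 1:4),
    compliance_flag = TRUE,
    event_stress = c(0.2, 0.4, 0.6, 0.5))
  expect_warning(out <- person_center(sc, scales = "event_stress"), "B")
  expect_equal(out$event_stress_pc, c(-0.2, 0, 0.2))
  # cohort level: every participant's centered mean is zero
  tab <- ema_table()
  means <- tapply(tab$na_pc, tab$participant_id, mean, na.rm = TRUE)
  expect_true(all(abs(means) < 1e-9))
  # constant scale -> centered all zero
  sc2 <- tibble::tibble(participant_id = "A", beep_id = c("b1", "b2"),
                        compliance_flag = TRUE, pa = c(0.5, 0.5))
  expect_equal(person_center(sc2, "pa")$pa_pc, c(0, 0))
})

test_that("median-split incongruence matches separable and shuffled oracles", {
  # perfectly separable: all stress-week aggregates above all control
  n <- 20
  sc <- tibble::tibble(
    participant_id = "P1", beep_id = sprintf("b%d", 1:n),
    week_type = rep(c("control", "stress"), each = n / 2),
    compliance_flag = TRUE,
    event_stress = rep(c(0.1, 0.9), each = n / 2),
    social_stress = rep(c(0.1, 0.9), each = n / 2),
    activity_stress = rep(c(0.1, 0.9), each = n / 2))
  res <- median_split_incongruence(sc)
  # only the median-tie beeps can be misassigned
  expect_lte(res$pooled, 0.5 / 2)
  # label shuffling -> about 50% incongruent (permutation oracle)
  tab <- ema_table()
  fracs <- withr::with_seed(99, replicate(20, {
    shuffled <- tab
    shuffled$week_type <- unlist(tapply(tab$week_type, tab$participant_id,
                                        sample), use.names = FALSE)
    median_split_incongruence(shuffled)$pooled
  }))
  expect_equal(mean(fracs), 0.5, tolerance = 0.02)
  # reference effects: well below 50%, well above 0
  frac <- median_split_incongruence(tab)$pooled
  expect_lt(frac, 0.5)
  expect_gt(frac, 0.2)
})
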