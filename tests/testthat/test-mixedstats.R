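# Mixed-effects week and momentary models, FDR correction, mediation.

test_that("week model preconditions and null-effect behaviour", {
  tab <- ema_table()
  expect_error(fit_week_model(tab[tab$participant_id == "P001", ], "na"),
               "2 participants")
  expect_error(fit_week_model(tab, "nonexistent_outcome"), "missing")
  # social stress has a configured week effect of zero
  fx <- fit_week_model(tab, "social_stress")
  r <- fx[fx$term == "week_type:stress", ]
  expect_lt(abs(r$estimate), 3 * r$se)
  expect_true(r$ci_low <= r$estimate && r$estimate <= r$ci_high)
})

test_that("week model recovers a configured effect at moderate n", {
  tab <- ema_table()   # 25 participants, reference effects
  fx <- fit_week_model(tab, "activity_stress")
  r <- fx[fx$term == "week_type:stress", ]
  expect_equal(r$estimate, 0.51, tolerance = 0.25)
  expect_equal(r$family, "gaussian")
  # counts refuse non-integer outcomes
  expect_error(fit_week_model(tab, "pa", family = "poisson"), "integer")
})

test_that("momentary model recovers the social-stress association and is
           invariant to beep order", {
  tab <- ema_table()
  mm <- fit_momentary_model(tab, "na", "social_stress")
  r <- mm[mm$term == "social_stress", ]
  expect_equal(r$estimate, 0.22, tolerance = 0.06)
  # uncorrelated predictor: hunger is generated independently of affect
  tab$hunger_pc <- tab$hunger - stats::ave(tab$hunger, tab$participant_id)
  m0 <- fit_momentary_model(tab, "na", "hunger",
                            covariates = setdiff(default_covariates(), "hunger"))
  r0 <- m0[m0$term == "hunger", ]
  expect_lt(abs(r0$estimate), 3 * r0$se)
  # permutation invariance: shuffling rows within participants changes nothing
  shuf <- withr::with_seed(5, tab[order(tab$participant_id,
                                        stats::runif(nrow(tab))), ])
  mm2 <- fit_momentary_model(shuf, "na", "social_stress")
  expect_equal(mm2$estimate[mm2$term == "social_stress"], r$estimate,
               tolerance = 1e-6)
})

test_that("BH correction matches hand computation and is monotone", {
  expect_equal(fdr_correct(0.03), 0.03)
  # hand BH: p * n / rank, cumulative minimum from the largest
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_correct(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.01, 0.04, 0.2, 0.6)
  adj <- fdr_correct(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= 0))
  # grouping corrects within families only
  g <- c(1, 1, 2, 2)
  expect_equal(fdr_correct(c(0.01, 0.02, 0.01, 0.02), g)[1:2],
               fdr_correct(c(0.01, 0.02)))
  expect_error(fdr_correct(c(0.5, 1.2)), "0, 1")
})

test_that("mediation decomposition satisfies its identities and nulls", {
  co <- ema_cohort()
  feats <- memo("ema_feats", extract_epa_features(co))
  tab <- dplyr::left_join(analysis_table(co), feats,
                          by = c("participant_id", "beep_id"))
  md <- memo("ema_mediation", mediate(tab, n_boot = 400, seed = 3))
  expect_s3_class(md, "sw_mediation")
  expect_equal(md$total, md$indirect + md$direct, tolerance = 1e-9)
  expect_true(md$indirect_ci[1] <= md$indirect &
                md$indirect <= md$indirect_ci[2])
  # no-mediation null: mediator path b forced to zero in the generator
  eff0 <- default_effects()
  eff0$mediation$path_b <- 0
  eff0 <- effect_config(week_effects = eff0$week_effects,
                        momentary_effects = eff0$momentary_effects,
                        mediation = eff0$mediation,
                        random_effect_sds = eff0$random_effect_sds,
                        physio = eff0$physio)
  co0 <- generate_cohort(study_config(n_participants = 14, seed = 19,
                                      n_faulty_temp = 0), eff0)
  tab0 <- dplyr::left_join(analysis_table(co0), extract_epa_features(co0),
                           by = c("participant_id", "beep_id"))
  md0 <- mediate(tab0, n_boot = 400, seed = 3)
  expect_true(md0$indirect_ci[1] <= 0 & 0 <= md0$indirect_ci[2])
})
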