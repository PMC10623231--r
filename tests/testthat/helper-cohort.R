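# Shared fixtures: small cohorts built once per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

small_config <- function(n = 4, days = 2, beeps = 3, seed = 11, ...) {
  study_config(n_participants = n, days_per_week = days, beeps_per_day = beeps,
               n_faulty_temp = 0, seed = seed, ...)
}

small_cohort <- function() {
  memo("small_cohort", generate_cohort(small_config()))
}

# a mid-sized EMA-only cohort for scoring/model tests (no physio needed)
ema_cohort <- function() {
  memo("ema_cohort",
       generate_cohort(study_config(n_participants = 25, seed = 42,
                                    n_faulty_temp = 0)))
}

ema_table <- function() {
  memo("ema_table", analysis_table(ema_cohort()))
}

# null-effect configuration: every configured effect and momentary path zero
null_effects <- function() {
  eff <- default_effects()
  for (k in names(eff$week_effects)) eff$week_effects[[k]] <- 0
  effect_config(
    week_effects = eff$week_effects,
    momentary_effects = list(),
    mediation = list(path_a = 0, path_b = 0, direct = 0),
    random_effect_sds = eff$random_effect_sds,
    item_noise_sd = eff$item_noise_sd,
    physio = eff$physio
  )
}
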