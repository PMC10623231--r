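# Reference "true" effect configuration for the synthetic cohort.
# Week effects and momentary associations are standardized coefficients on
# the scored outcomes (log scale for the SCR count); the generator's variance
# budget makes them directly recoverable by the mixed models.
week_effects:
  event_stress: 0.30
  activity_stress: 0.51
  social_stress: 0.0
  physical_stress: 0.0
  "na": 0.12
  pa: -0.08
  scr_count_log: -0.27
  hr_max: -0.10
momentary_effects:
  "na":
    activity_stress: 0.06
    social_stress: 0.22
    physical_stress: 0.15
  pa:
    event_stress: -0.12
    activity_stress: -0.17
    social_stress: -0.28
    physical_stress: -0.23
mediation:
  path_a: -0.08      # week -> positive affect (equals week_effects.pa)
  path_b: 0.1625     # positive affect -> SCR magnitude; indirect = -0.013
  direct: -0.166     # week -> SCR magnitude given positive affect
random_effect_sds:
  intercept:
    event_stress: 0.45
    activity_stress: 0.45
    social_stress: 0.45
    physical_stress: 0.45
    "na": 0.50
    pa: 0.50
    scr_count_log: 0.40
    scr_magnitude: 0.30
  # Per-participant week-effect SDs. Not printed by the studies this
  # configuration mirrors; chosen so individualized (within-person)
  # classifiability sits in the published regime: affect carries more
  # individual week signal than physiology, and both are well above chance.
  slope:
    event_stress: 0.20
    activity_stress: 0.25
    social_stress: 0.20
    physical_stress: 0.20
    "na": 0.55
    pa: 0.15
    scr_count_log: 0.0
    scr_magnitude: 0.15
    hr_max: 0.08
item_noise_sd: 0.3
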