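#' Study design configuration
#'
#' Describes the two-week naturalistic design: every participant completes one
#' examination ("stress") week and one control week, with a fixed number of
#' EMA surveys ("beeps") per day, a one-hour response window, and a wrist
#' sensor recording EDA, heart rate, skin temperature and 3-axis acceleration
#' throughout the day. Probabilities control realized EMA compliance and the
#' availability of usable physiology given a completed survey.
#'
#' @param n_participants Number of participants (default 83).
#' @param days_per_week Days per study arm (default 7).
#' @param beeps_per_day Surveys per day (default 6, 09:00 to 21:30 in 2.5 h
#'   steps).
#' @param beep_window Response window in seconds (default 3600).
#' @param epa_window Pre-beep physiology window in seconds (default 600).
#' @param sample_rates Named list of channel sample rates in Hz
#'   (`eda`, `hr`, `temp`, `acc`); interbeat intervals are event-based.
#' @param ema_compliance Probability a scheduled beep is answered within the
#'   response window (default 0.85).
#' @param epa_availability_given_ema Probability the pre-beep sensor window is
#'   usable given a compliant beep (default 0.905, joint availability about
#'   0.77).
#' @param prop_stress_week_first Probability the stress week comes first
#'   (default 27/83).
#' @param n_faulty_temp Number of participants whose watch has a dead
#'   temperature sensor (default 2); their temperature features are imputed
#'   from the population.
#' @param ibi_coverage Fraction of each pre-beep window covered by detected
#'   interbeat intervals (default 0.27).
#' @param seed Integer seed controlling the whole cohort.
#' @return A list of class `sw_study_config`.
#' @export
study_config <- function(n_participants = 83,
                         days_per_week = 7,
                         beeps_per_day = 6,
                         beep_window = 3600,
                         epa_window = 600,
                         sample_rates = list(eda = 4, hr = 1, temp = 4, acc = 32),
                         ema_compliance = 0.85,
                         epa_availability_given_ema = 0.905,
                         prop_stress_week_first = 27 / 83,
                         n_faulty_temp = 2,
                         ibi_coverage = 0.27,
                         seed = 1L) {
  cfg <- list(
    n_participants = check_count(n_participants, "n_participants"),
    n_weeks_per_arm = 1L,
    days_per_week = check_count(days_per_week, "days_per_week"),
    beeps_per_day = check_count(beeps_per_day, "beeps_per_day"),
    beep_window = check_pos(beep_window, "beep_window"),
    epa_window = check_pos(epa_window, "epa_window"),
    sample_rates = sample_rates,
    ema_compliance = check_prob(ema_compliance, "ema_compliance"),
    epa_availability_given_ema =
      check_prob(epa_availability_given_ema, "epa_availability_given_ema"),
    prop_stress_week_first =
      check_prob(prop_stress_week_first, "prop_stress_week_first"),
    n_faulty_temp = check_count(n_faulty_temp, "n_faulty_temp", min = 0),
    ibi_coverage = check_prob(ibi_coverage, "ibi_coverage"),
    seed = check_count(seed, "seed", min = 0)
  )
  for (ch in c("eda", "hr", "temp", "acc")) {
    r <- sample_rates[[ch]]
    if (is.null(r) || !is.numeric(r) || r <= 0)
      stop_config(paste0("sample_rates$", ch), "must be a rate > 0 in Hz")
  }
  if (cfg$n_faulty_temp > cfg$n_participants)
    stop_config("n_faulty_temp", "cannot exceed n_participants")
  structure(cfg, class = "sw_study_config")
}

# fixed daily beep clock times (seconds after midnight): 09:00 to 21:30 in
# 2.5 h steps for the default 6 beeps; other counts spread evenly in the
# same 09:00-21:30 span
beep_times_of_day <- function(beeps_per_day) {
  if (beeps_per_day == 1) return(9 * 3600)
  seq(9 * 3600, 21.5 * 3600, length.out = beeps_per_day)
}

#' EMA scale map
#'
#' The default item-to-scale map: four stress appraisal scales (event,
#' activity, social, physical; three 7-point items each, one reversed) and
#' PANAS-style positive (4 items) and negative (5 items) affect, each with
#' one reversed item. Reversed items are emitted inverted by the generator
#' and re-inverted during scoring.
#'
#' @return Named list; each element has `items` (character) and `reversed`
#'   (character subset of `items`).
#' @export
default_scale_map <- function() {
  list(
    event_stress    = list(items = paste0("event_", 1:3),    reversed = "event_3"),
    activity_stress = list(items = paste0("activity_", 1:3), reversed = "activity_3"),
    social_stress   = list(items = paste0("social_", 1:3),   reversed = "social_3"),
    physical_stress = list(items = paste0("physical_", 1:3), reversed = "physical_3"),
    pa              = list(items = paste0("pa_", 1:4),       reversed = "pa_4"),
    na              = list(items = paste0("na_", 1:5),       reversed = "na_5")
  )
}

ema_scales <- function() names(default_scale_map())

#' Effect configuration for the synthetic cohort
#'
#' Collects the "true" effect structure the generator encodes and the
#' downstream models recover: standardized week-type effects per outcome,
#' momentary within-beep stress-to-affect coefficients, the mediation paths
#' from week type through positive affect to skin-conductance-response
#' magnitude, per-participant random-effect SDs, and the physiological signal
#' parameters. All EMA and z-scored physiological effects are expressed in SD
#' units of the *scored* outcome; the generator solves a variance budget so
#' that the scored outcome has unit variance, which makes configured
#' standardized coefficients directly recoverable by the mixed models.
#'
#' @param week_effects Named list of standardized week-type coefficients
#'   (`event_stress`, `activity_stress`, `social_stress`, `physical_stress`,
#'   `na`, `pa`, `scr_count_log` on the log scale, `hr_max`).
#' @param momentary_effects Nested list `outcome -> stress scale ->
#'   coefficient` for within-beep associations.
#' @param mediation List with `path_a` (week to PA; must equal
#'   `week_effects$pa`), `path_b` (PA to SCR magnitude) and `direct` (week to
#'   SCR magnitude given PA). The indirect effect is `path_a * path_b`.
#' @param random_effect_sds List with `intercept` and `slope` named lists of
#'   per-participant SDs (SD units of the scored outcome; log scale for
#'   `scr_count_log`).
#' @param item_noise_sd SD of item-specific noise on the latent z scale.
#' @param physio Named list of physiological signal parameters; see
#'   [default_effects()] for the shipped values.
#' @param sign_flip If `TRUE`, every participant's week-type effect directions
#'   (all outcomes) are multiplied by an independent random sign: a
#'   constructed-heterogeneity regime in which group-level models carry no
#'   consistent signal while individualized models do.
#' @return A list of class `sw_effect_config`.
#' @seealso [default_effects()], [heterogeneous_effects()]
#' @export
effect_config <- function(week_effects,
                          momentary_effects = list(),
                          mediation = list(path_a = week_effects$pa %||% 0,
                                           path_b = 0, direct = 0),
                          random_effect_sds,
                          item_noise_sd = 0.3,
                          physio = default_physio(),
                          sign_flip = FALSE) {
  need <- c("event_stress", "activity_stress", "social_stress",
            "physical_stress", "na", "pa", "scr_count_log", "hr_max")
  for (k in need)
    if (is.null(week_effects[[k]]))
      stop_config(paste0("week_effects$", k), "is required (use 0 for none)")
  med <- mediation
  for (k in c("path_a", "path_b", "direct"))
    if (is.null(med[[k]])) stop_config(paste0("mediation$", k), "is required")
  if (abs(med$path_a - week_effects$pa) > 1e-9)
    stop_config("mediation$path_a",
                "must equal week_effects$pa (week-to-PA path)")
  med$indirect <- med$path_a * med$path_b
  for (grp in c("intercept", "slope"))
    if (is.null(random_effect_sds[[grp]]))
      stop_config(paste0("random_effect_sds$", grp), "is required")
  ph <- utils::modifyList(default_physio(), physio)
  structure(
    list(week_effects = week_effects,
         momentary_effects = momentary_effects,
         mediation = med,
         random_effect_sds = random_effect_sds,
         item_noise_sd = check_pos(item_noise_sd, "item_noise_sd"),
         physio = ph,
         sign_flip = isTRUE(sign_flip)),
    class = "sw_effect_config")
}

# physiological signal parameters: levels and noise chosen to resemble
# wrist-worn recordings (tonic EDA about 1 uS, HR about 75 bpm, skin
# temperature about 33 C); see the methods vignette for rationale
default_physio <- function() {
  list(
    scr_rate_per_window = 2.4,   # control-week mean SCR count per 10-min window
    scr_amp_mean = 0.4,          # uS, mean SCR amplitude
    scr_amp_scale = 0.12,        # uS per SD of the latent magnitude state
    scr_amp_jitter = 0.05,       # uS, event-to-event amplitude noise
    scr_amp_floor = 0.05,        # uS, smallest emitted amplitude
    dynamic_range_sdlog = 0.2,   # between-participant log-SD of SCR amplitude scaling
    eda_noise_sd = 0.002,        # uS, white measurement noise (near the
                                 # device's ~1 nS quantization floor)
    tonic_mean = 1.2,            # uS
    tonic_between_sd = 0.35,     # uS, between-participant tonic level SD
    tonic_drift_sd = 0.08,       # uS, slow within-day drift SD
    bad_contact_level = 0.004,   # uS, flat level during poor electrode contact
    hr_base_mean = 75,           # bpm
    hr_base_sd = 5,              # bpm, between participants
    hr_drift_sd = 3,             # bpm, slow within-day drift SD
    hr_noise_sd = 4,             # bpm, sample-to-sample noise
    temp_base_mean = 33,         # C
    temp_base_sd = 0.4,          # C, between participants
    temp_drift_sd = 0.3,         # C, within-day drift SD
    temp_noise_sd = 0.02,        # C
    acc_noise_sd = 0.02,         # g, wrist noise inside analysis windows
    burst_rate_per_hour = 2,     # motion bursts per hour
    burst_acc_sd = 0.4,          # g, acceleration noise during a burst
    burst_eda_amp = c(0.1, 0.8), # uS, uniform range of co-timed EDA spikes
    burst_eda_width = 2,         # samples (at the EDA rate), spike width <= 0.5 s
    ibi_mean = 0.8,              # s, mean interbeat interval
    ibi_sd = 0.05                # s
  )
}

#' Shipped default effect configuration
#'
#' Reads `effects_default.yaml` from the package: the reference set of true
#' effects the generator defaults to, matching the published estimates from
#' the examination-week study design this package emulates (for example
#' event-related stress 0.30 SD, activity stress 0.51 SD, negative affect
#' 0.12 SD, positive affect -0.08 SD, SCR count -0.27 on the log scale,
#' maximum HR -0.10 SD, and mediation paths giving an indirect effect of
#' -0.013 and a direct effect of -0.166).
#'
#' @param path Optional path to an alternative YAML file.
#' @return An `sw_effect_config`.
#' @export
default_effects <- function(path = NULL) {
  path <- path %||% system.file("extdata", "effects_default.yaml",
                                package = "stressweek", mustWork = TRUE)
  y <- yaml::read_yaml(path)
  effect_config(
    week_effects = y$week_effects,
    momentary_effects = y$momentary_effects %||% list(),
    mediation = y$mediation,
    random_effect_sds = y$random_effect_sds,
    item_noise_sd = y$item_noise_sd %||% 0.3,
    physio = y$physio %||% list()
  )
}

#' Constructed-heterogeneity effect configuration
#'
#' A stress-test variant of [default_effects()] in which each participant's
#' week-effect directions are sign-flipped for a randomly chosen half of
#' the cohort and the per-participant random slopes are raised to near the
#' variance-budget ceiling (with the SCR base rate at 6 per window).
#' Individualized (leave-one-beep-out)
#' models retain strong within-person signal, while group-level
#' (leave-one-subject-out) models face a cohort with no consistent effect
#' direction and fall to chance: the regime that reproduces the
#' individualized-beats-group phenomenon by construction.
#'
#' @param base Effect configuration to start from.
#' @return An `sw_effect_config` with `sign_flip = TRUE`.
#' @export
heterogeneous_effects <- function(base = default_effects()) {
  sds <- base$random_effect_sds
  # per-participant week effects near the variance-budget ceiling: every
  # participant is strongly (but idiosyncratically) week-separable
  sds$slope <- list(event_stress = 0.7, activity_stress = 0.7,
                    social_stress = 0.7, physical_stress = 0.7,
                    na = 1.0, pa = 0.8,
                    # the count slope stays 0: symmetric log effects would
                    # leave a group-learnable convexity signature in the
                    # counts; the linear channels carry the physio signal
                    scr_count_log = 0, scr_magnitude = 1.2, hr_max = 0.8)
  ph <- base$physio
  ph$scr_rate_per_window <- 6
  effect_config(
    week_effects = base$week_effects,
    momentary_effects = base$momentary_effects,
    mediation = base$mediation,
    random_effect_sds = sds,
    item_noise_sd = base$item_noise_sd,
    physio = ph,
    sign_flip = TRUE
  )
}

# ---- generative calibration -------------------------------------------------

# Variance budget for one scored EMA scale. Items are produced by
# equal-width discretization of (4 + latent + item noise) onto 1..7, so the
# scored (rescaled) scale carries, per item, the item noise variance plus the
# rounding variance 1/12. The budget solves for the residual SD that makes
# the scored outcome have unit variance, so configured standardized effects
# are recovered without attenuation.
ema_budget <- function(effects, scale, k_items) {
  bw <- effects$week_effects[[scale]] %||% 0
  s0 <- effects$random_effect_sds$intercept[[scale]] %||% 0
  s1 <- effects$random_effect_sds$slope[[scale]] %||% 0
  mom <- effects$momentary_effects[[scale]]
  bmom2 <- if (is.null(mom)) 0 else sum(unlist(mom)^2)
  meas <- (effects$item_noise_sd^2 + 1 / 12) / k_items
  fixed <- s0^2 + s1^2 / 2 + bw^2 / 4 + bmom2 + meas
  if (fixed > 0.95)
    stop_config(scale, sprintf(
      "variance budget exceeded (fixed components %.2f of unit variance); reduce effect or random-effect SDs",
      fixed))
  list(beta_week = bw, sd_intercept = s0, sd_slope = s1,
       sigma_resid = sqrt(1 - fixed), meas_var = meas,
       within_sd = sqrt(1 - fixed + meas))   # sd of the observed residual deviation
}

# all per-outcome generative parameters, resolved once per cohort
gen_params <- function(effects, scale_map = default_scale_map()) {
  scales <- names(scale_map)
  budgets <- lapply(scales, function(s)
    ema_budget(effects, s, length(scale_map[[s]]$items)))
  names(budgets) <- scales

  ph <- effects$physio
  # latent SCR-magnitude state: unit-variance budget as for EMA scales
  med <- effects$mediation
  s0m <- effects$random_effect_sds$intercept[["scr_magnitude"]] %||% 0
  s1m <- effects$random_effect_sds$slope[["scr_magnitude"]] %||% 0
  fixed_m <- med$direct^2 / 4 + med$path_b^2 + s0m^2 + s1m^2 / 2
  if (fixed_m > 0.95) stop_config("scr_magnitude", "variance budget exceeded")
  sigma_m <- sqrt(1 - fixed_m)

  # maximum-HR calibration: the window maximum of iid Gaussian samples has
  # SD approximately 0.367 * noise SD at 600 samples (Gumbel tail of the
  # sample maximum); the week effect is configured in SD units of the
  # realized per-window maximum and converted to bpm here
  n_hr <- 600
  max_sd_factor <- 0.367
  var_base <- ph$hr_base_sd^2 + ph$hr_drift_sd^2 +
    (max_sd_factor * ph$hr_noise_sd)^2
  bw_hr <- effects$week_effects$hr_max
  s1_hr <- effects$random_effect_sds$slope[["hr_max"]] %||% 0
  denom <- 1 - bw_hr^2 / 4 - s1_hr^2 / 2
  sd_hrmax <- sqrt(var_base / denom)
  list(
    budgets = budgets,
    sigma_magnitude = sigma_m,
    sd_hrmax = sd_hrmax,
    hr_week_bpm = bw_hr * sd_hrmax,
    hr_slope_bpm = s1_hr * sd_hrmax,
    n_hr_window = n_hr
  )
}
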