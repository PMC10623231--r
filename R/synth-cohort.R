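# Synthetic cohort generation: participants, beep schedules, EMA responses
# and the latent physiological states consumed by the sensor simulator.

EPOCH_ORIGIN <- 1578268800  # 2020-01-06 00:00 UTC, a Monday

#' Generate a synthetic two-week EMA + wearable cohort
#'
#' Produces a full cohort for the two-arm design: every participant is
#' scheduled for `days_per_week * beeps_per_day` beeps in each of a stress
#' (examination) week and a control week, answers each beep with probability
#' `ema_compliance`, and carries per-participant random effects drawn from
#' the configured SDs. Scored EMA scales, skin-conductance response counts
#' and amplitudes, and heart-rate shifts encode the configured week-type,
#' momentary and mediation effects, so downstream models can be validated by
#' parameter recovery. Sensor streams are simulated per day by
#' [simulate_physio_day()] from the latent states stored in `$truth`.
#'
#' @param config An [study_config()].
#' @param effects An [effect_config()]; defaults to the shipped reference
#'   configuration.
#' @return An object of class `sw_cohort`: a list with `participants`,
#'   `ema` (long beep table with item and covariate columns), `truth`
#'   (per-beep latent states and ground-truth SCR events, for testing),
#'   `config`, `effects`, `gen` (resolved generative parameters) and
#'   `scale_map`.
#' @examples
#' cohort <- generate_cohort(study_config(n_participants = 2, days_per_week = 2,
#'                                        beeps_per_day = 3, seed = 7))
#' nrow(cohort$ema)  # 2 participants x 2 arms x 2 days x 3 beeps
#' @export
generate_cohort <- function(config = study_config(),
                            effects = default_effects()) {
  stopifnot(inherits(config, "sw_study_config"),
            inherits(effects, "sw_effect_config"))
  gp <- gen_params(effects)
  scale_map <- default_scale_map()
  participants <- draw_participants(config, effects, gp)
  per <- lapply(seq_len(config$n_participants), function(i)
    simulate_participant(participants[i, ], config, effects, gp, scale_map))
  ema <- dplyr::bind_rows(lapply(per, `[[`, "ema"))
  truth <- dplyr::bind_rows(lapply(per, `[[`, "truth"))
  structure(list(config = config, effects = effects, gen = gp,
                 participants = participants, ema = ema, truth = truth,
                 scale_map = scale_map),
            class = "sw_cohort")
}

#' @export
print.sw_cohort <- function(x, ...) {
  cat(sprintf(
    "<sw_cohort> %d participants, %d scheduled beeps (%d answered in window)\n",
    x$config$n_participants, nrow(x$ema),
    sum(!is.na(x$ema$completed_time) &
          x$ema$completed_time - x$ema$scheduled_time <= x$config$beep_window)))
  invisible(x)
}

outcome_names <- function() c(ema_scales(), "scr_count_log", "scr_magnitude")

draw_participants <- function(config, effects, gp) {
  n <- config$n_participants
  sds <- effects$random_effect_sds
  ph <- effects$physio
  withr::with_seed(derive_seed(config$seed, "participants"), {
    out <- tibble::tibble(
      participant_id = sprintf("P%03d", seq_len(n)),
      sex = ifelse(stats::runif(n) < 0.614, "female", "male"),
      program = ifelse(stats::runif(n) < 0.735, "medicine", "biomedical"),
      stress_week_first = stats::runif(n) < config$prop_stress_week_first,
      # balanced random sign flips: equal halves, random assignment, so the
      # cohort-level effect is null by construction, not just on average
      sign = if (effects$sign_flip) sample(rep(c(-1, 1), length.out = n))
             else rep(1, n),
      faulty_temp = seq_len(n) %in%
        sample(seq_len(n), min(config$n_faulty_temp, n)),
      range_amp = exp(stats::rnorm(n, 0, ph$dynamic_range_sdlog)),
      tonic_level = pmax(0.2, stats::rnorm(n, ph$tonic_mean, ph$tonic_between_sd)),
      hr_base = stats::rnorm(n, ph$hr_base_mean, ph$hr_base_sd),
      temp_base = stats::rnorm(n, ph$temp_base_mean, ph$temp_base_sd)
    )
    # random intercepts are Gaussian; random week slopes are two-point
    # (+/- SD): individual week effects of near-constant magnitude and
    # random direction, matching the tight spread of individualized
    # classification errors this design is known for (zero mean, so
    # population fixed effects are unaffected)
    # In the sign-flip (constructed-heterogeneity) regime all of a
    # participant's slopes share their flip direction: the two half-cohorts
    # are exact mirrors, so no feature pattern generalizes across
    # participants even jointly.
    for (o in outcome_names()) {
      out[[paste0("u0_", o)]] <-
        stats::rnorm(n, 0, sds$intercept[[o]] %||% 0)
      slope_dir <- if (effects$sign_flip) out$sign
                   else sample(c(-1, 1), n, replace = TRUE)
      out[[paste0("u1_", o)]] <- (sds$slope[[o]] %||% 0) * slope_dir
    }
    out$u1_hr_bpm <- gp$hr_slope_bpm *
      (if (effects$sign_flip) out$sign else sample(c(-1, 1), n, replace = TRUE))
    out
  })
}

# schedule for one participant: one row per scheduled beep across both arms
build_schedule <- function(prow, config) {
  tod <- beep_times_of_day(config$beeps_per_day)
  arms <- if (prow$stress_week_first) c("stress", "control") else c("control", "stress")
  grid <- expand.grid(beep_index_in_day = seq_len(config$beeps_per_day),
                      day_index = seq_len(config$days_per_week),
                      week_index = 1:2)
  grid$week_type <- arms[grid$week_index]
  # arms separated by a full recovery week
  grid$scheduled_time <- EPOCH_ORIGIN +
    (grid$week_index - 1) * 14 * 86400 +
    (grid$day_index - 1) * 86400 +
    tod[grid$beep_index_in_day]
  grid$beep_id <- sprintf("%s_w%d_d%d_b%d", prow$participant_id,
                          grid$week_index, grid$day_index,
                          grid$beep_index_in_day)
  tibble::as_tibble(grid)
}

# discretize latent z values onto the 7-point scale for one item
likert_item <- function(z) pmin(7L, pmax(1L, as.integer(round(4 + z))))

# simulate all items of one scale for a vector of beep-level latents;
# returns the matrix of *emitted* items (reversed items inverted) plus the
# rescaled score computed exactly as the scoring module would
sim_scale_items <- function(latent, items, reversed, item_noise_sd) {
  n <- length(latent)
  k <- length(items)
  v <- matrix(0L, n, k, dimnames = list(NULL, items))
  for (j in seq_len(k))
    v[, j] <- likert_item(latent + stats::rnorm(n, 0, item_noise_sd))
  raw <- rowSums(v)                    # scoring re-inverts, recovering v
  rescaled <- (raw - k) / (6 * k)
  emitted <- v
  rev_idx <- which(items %in% reversed)
  for (j in rev_idx) emitted[, j] <- 8L - emitted[, j]
  list(emitted = emitted, rescaled = rescaled)
}

#' Simulate the raw item responses of a single EMA beep
#'
#' Given per-scale latent values on the z scale, draws item-level noise,
#' discretizes onto the 7-point scale with equal-width thresholds, and emits
#' reversed-scale items inverted (`v -> 8 - v`), exactly as the cohort
#' generator does internally.
#'
#' @param latents Named numeric vector or list of latent values, one per
#'   scale in `scale_map`.
#' @param scale_map Item map, see [default_scale_map()].
#' @param item_noise_sd Item-specific noise SD.
#' @return Named integer vector of emitted item responses in 1..7.
#' @export
simulate_ema_response <- function(latents, scale_map = default_scale_map(),
                                  item_noise_sd = 0.3) {
  out <- integer(0)
  for (s in names(scale_map)) {
    if (is.null(latents[[s]])) stop_config(s, "latent value missing")
    sim <- sim_scale_items(latents[[s]], scale_map[[s]]$items,
                           scale_map[[s]]$reversed, item_noise_sd)
    out <- c(out, stats::setNames(as.integer(sim$emitted[1, ]),
                                  scale_map[[s]]$items))
  }
  out
}

simulate_participant <- function(prow, config, effects, gp, scale_map) {
  sched <- build_schedule(prow, config)
  n <- nrow(sched)
  W <- as.numeric(sched$week_type == "stress")
  sgn <- prow$sign
  ph <- effects$physio
  med <- effects$mediation

  withr::with_seed(derive_seed(config$seed, "ema", prow$participant_id), {
    # -- compliance and covariates ------------------------------------------
    u <- stats::runif(n)
    pc <- config$ema_compliance
    status <- ifelse(u < pc, "compliant",
                     ifelse(u < pc + (1 - pc) / 2, "late", "missing"))
    completed <- rep(NA_real_, n)
    idx <- status == "compliant"
    completed[idx] <- sched$scheduled_time[idx] +
      stats::runif(sum(idx), 0, 0.95 * config$beep_window)
    idx <- status == "late"
    completed[idx] <- sched$scheduled_time[idx] +
      config$beep_window * (1 + stats::runif(sum(idx)))

    n_days <- config$days_per_week * 2
    day_key <- (sched$week_index - 1) * config$days_per_week + sched$day_index
    sleep_by_day <- stats::rnorm(n_days, 7.5, 1)
    alcohol_by_day <- stats::rpois(n_days, 0.3)
    covars <- tibble::tibble(
      sleep_duration = round(sleep_by_day[day_key], 2),
      alcohol_units = alcohol_by_day[day_key],
      hunger = sample(1:7, n, replace = TRUE),
      caffeine = stats::rbinom(n, 1, 0.3),
      exercise = stats::rbinom(n, 1, 0.15),
      sexual_activity = stats::rbinom(n, 1, 0.05),
      ambient_temperature = round(stats::rnorm(n, 20, 3), 1)
    )

    # -- stress appraisal scales --------------------------------------------
    items <- list()
    latents <- list()
    dev_std <- list()
    stress_scales <- setdiff(ema_scales(), c("pa", "na"))
    for (s in stress_scales) {
      b <- gp$budgets[[s]]
      bw <- sgn * b$beta_week
      u0 <- prow[[paste0("u0_", s)]]
      u1 <- prow[[paste0("u1_", s)]]
      lat <- bw * W + u0 + u1 * W + stats::rnorm(n, 0, b$sigma_resid)
      sim <- sim_scale_items(lat, scale_map[[s]]$items, scale_map[[s]]$reversed,
                             effects$item_noise_sd)
      # observed residual deviation of the scored scale, in latent units,
      # standardized by its analytic within-SD: drives momentary associations
      dev <- 6 * (sim$rescaled - 0.5) - u0 - (bw + u1) * W
      dev_std[[s]] <- dev / b$within_sd
      items[[s]] <- sim$emitted
      latents[[s]] <- lat
    }

    # -- affect scales (receive momentary stress input) ---------------------
    for (s in c("na", "pa")) {
      b <- gp$budgets[[s]]
      bw <- sgn * b$beta_week
      u0 <- prow[[paste0("u0_", s)]]
      u1 <- prow[[paste0("u1_", s)]]
      mom <- effects$momentary_effects[[s]]
      drive <- rep(0, n)
      if (!is.null(mom))
        for (sc in names(mom)) drive <- drive + mom[[sc]] * dev_std[[sc]]
      lat <- bw * W + u0 + u1 * W + drive + stats::rnorm(n, 0, b$sigma_resid)
      sim <- sim_scale_items(lat, scale_map[[s]]$items, scale_map[[s]]$reversed,
                             effects$item_noise_sd)
      items[[s]] <- sim$emitted
      latents[[s]] <- lat
      if (s == "pa") pa_obs <- 6 * (sim$rescaled - 0.5)
    }

    # -- latent physiological states ----------------------------------------
    lambda <- ph$scr_rate_per_window *
      exp(sgn * effects$week_effects$scr_count_log * W +
            prow$u0_scr_count_log + prow$u1_scr_count_log * W)
    scr_count_true <- stats::rpois(n, lambda)
    m_z <- sgn * med$direct * W + med$path_b * pa_obs +
      prow$u0_scr_magnitude + prow$u1_scr_magnitude * W +
      stats::rnorm(n, 0, gp$sigma_magnitude)
    event_offsets <- vector("list", n)
    event_amps <- vector("list", n)
    for (i in seq_len(n)) {
      k <- scr_count_true[i]
      event_offsets[[i]] <- sort(stats::runif(k, 5, config$epa_window - 20))
      event_amps[[i]] <- prow$range_amp *
        pmax(ph$scr_amp_floor,
             ph$scr_amp_mean + ph$scr_amp_scale * m_z[i] +
               stats::rnorm(k, 0, ph$scr_amp_jitter))
    }
    hr_shift_bpm <- (sgn * gp$hr_week_bpm + prow$u1_hr_bpm) * W
    epa_contact <- stats::runif(n) < config$epa_availability_given_ema

    # -- assemble -----------------------------------------------------------
    item_mat <- do.call(cbind, items[ema_scales()])
    item_tbl <- tibble::as_tibble(item_mat)
    item_tbl[status == "missing", ] <- NA_integer_

    ema <- dplyr::bind_cols(
      tibble::tibble(
        participant_id = prow$participant_id,
        beep_id = sched$beep_id,
        week_type = sched$week_type,
        week_index = sched$week_index,
        day_index = sched$day_index,
        beep_index_in_day = sched$beep_index_in_day,
        scheduled_time = sched$scheduled_time,
        completed_time = completed,
        sex = prow$sex,
        program = prow$program,
        stress_week_first = prow$stress_week_first
      ),
      covars, item_tbl)

    truth <- tibble::tibble(
      participant_id = prow$participant_id,
      beep_id = sched$beep_id,
      week_type = sched$week_type,
      week_index = sched$week_index,
      day_index = sched$day_index,
      scheduled_time = sched$scheduled_time,
      m_z = m_z,
      lambda = lambda,
      scr_count_true = scr_count_true,
      event_offsets = event_offsets,
      event_amps = event_amps,
      hr_shift_bpm = hr_shift_bpm,
      epa_contact = epa_contact,
      pa_obs_latent = pa_obs
    )
    for (s in ema_scales()) truth[[paste0("latent_", s)]] <- latents[[s]]

    list(ema = ema, truth = truth)
  })
}
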