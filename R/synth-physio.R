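# Continuous sensor-stream synthesis: one recording session per study day,
# in the wrist-device export dialect (per-channel sample vectors with a UTC
# start time and a fixed rate; event-based interbeat intervals).

#' Discrete Bateman impulse response
#'
#' The canonical skin-conductance-response shape: a difference of two
#' exponentials, `exp(-t / tau_decay) - exp(-t / tau_rise)`, sampled at
#' `rate` Hz and normalized to unit peak. Used both to synthesize SCRs and
#' to deconvolve measured EDA into tonic and phasic components.
#'
#' @param rate Sample rate in Hz.
#' @param tau_rise,tau_decay Rise and decay time constants in seconds
#'   (`0 < tau_rise < tau_decay`).
#' @return Numeric vector, the kernel truncated where the decay falls below
#'   1e-4 of the peak.
#' @export
bateman_kernel <- function(rate, tau_rise = 0.75, tau_decay = 2.0) {
  if (!(tau_rise > 0 && tau_decay > tau_rise))
    stop_config("bateman_tau", "requires 0 < tau_rise < tau_decay")
  t <- seq(0, tau_decay * log(1e4), by = 1 / rate)
  h <- exp(-t / tau_decay) - exp(-t / tau_rise)
  h / max(h)
}

# convolve an impulse train with the Bateman kernel via two first-order
# recursive filters (exact for the sampled kernel, O(n))
conv_bateman <- function(train, rate, tau_rise = 0.75, tau_decay = 2.0) {
  ad <- exp(-1 / (rate * tau_decay))
  ar <- exp(-1 / (rate * tau_rise))
  k <- seq(0, ceiling(tau_decay * log(1e4) * rate))
  peak <- max(ad^k - ar^k)
  y <- as.numeric(stats::filter(train, ad, method = "recursive")) -
    as.numeric(stats::filter(train, ar, method = "recursive"))
  y / peak
}

# slow smooth drift: spline through hourly Gaussian knots; split into a
# drawing step and an evaluation step so that full-day and window-segment
# generation consume identical RNG draws
drift_knots <- function(n, rate, sd) {
  k <- max(4, ceiling(n / rate / 3600) + 1)
  list(x = seq(1, n, length.out = k), y = stats::rnorm(k, 0, sd))
}

drift_eval <- function(kn, xout) {
  if (is.null(kn)) return(rep(0, length(xout)))
  stats::spline(kn$x, kn$y, xout = xout)$y
}

smooth_drift <- function(n, rate, sd) {
  if (sd <= 0 || n < 4) return(rep(0, n))
  drift_eval(drift_knots(n, rate, sd), seq_len(n))
}

#' Synthesize one EDA segment with known ground truth
#'
#' Low-level oracle generator used by the signal-processing tests: a flat (or
#' drifting) tonic baseline plus Bateman-shaped SCRs at given event times and
#' amplitudes, optional white noise, and optional square artifact spikes.
#'
#' @param duration Segment length in seconds.
#' @param rate Sample rate in Hz.
#' @param event_times Numeric vector of SCR onset times (s from segment start).
#' @param event_amps Amplitudes in microsiemens (recycled).
#' @param tonic Baseline level in microsiemens (scalar or vector of length
#'   `duration * rate`).
#' @param noise_sd White-noise SD in microsiemens.
#' @param spike_times,spike_amps,spike_width Optional artifact spikes:
#'   onset times (s), amplitudes (uS) and width in samples.
#' @param tau_rise,tau_decay Bateman time constants (s).
#' @param seed Optional seed for the noise.
#' @return Numeric vector of EDA samples (uS), length `duration * rate`.
#' @export
simulate_eda_segment <- function(duration, rate = 4, event_times = numeric(),
                                 event_amps = numeric(), tonic = 1.0,
                                 noise_sd = 0, spike_times = numeric(),
                                 spike_amps = numeric(), spike_width = 1,
                                 tau_rise = 0.75, tau_decay = 2.0,
                                 seed = NULL) {
  n <- round(duration * rate)
  train <- numeric(n)
  if (length(event_times)) {
    amps <- rep_len(event_amps, length(event_times))
    idx <- pmin(n, pmax(1, round(event_times * rate) + 1))
    for (j in seq_along(idx)) train[idx[j]] <- train[idx[j]] + amps[j]
  }
  x <- rep_len(tonic, n) + conv_bateman(train, rate, tau_rise, tau_decay)
  if (noise_sd > 0) {
    noise <- if (is.null(seed)) stats::rnorm(n, 0, noise_sd)
             else withr::with_seed(seed, stats::rnorm(n, 0, noise_sd))
    x <- x + noise
  }
  if (length(spike_times)) {
    amps <- rep_len(spike_amps, length(spike_times))
    for (j in seq_along(spike_times)) {
      i0 <- round(spike_times[j] * rate) + 1
      ii <- i0:min(n, i0 + spike_width - 1)
      x[ii] <- x[ii] + amps[j]
    }
  }
  pmax(x, 0)
}

sw_stream <- function(channel, start, rate, samples) {
  list(channel = channel, start = start, rate = rate, samples = samples)
}

#' Simulate the wearable recording of one study day
#'
#' Builds the continuous sensor streams for one participant-day: a single
#' session spanning from 15 minutes before the first beep to the last beep of
#' the day (the charging hour sits overnight, outside all analysis windows).
#' EDA is a slowly drifting tonic baseline plus Poisson-timed Bateman SCRs
#' whose per-window counts and amplitudes are the cohort's stored ground
#' truth, plus white noise and motion-burst spike artifacts; HR, skin
#' temperature and 3-axis acceleration are generated per channel; sparse
#' interbeat intervals cover a configurable fraction of each pre-beep window.
#' Windows flagged as poor electrode contact are overwritten with a flat
#' sub-threshold EDA level so the quality rules downstream exclude them.
#'
#' @param cohort An `sw_cohort`.
#' @param participant_id Participant identifier.
#' @param week_index Arm index (1 or 2).
#' @param day_index Day within the arm.
#' @param channels Channels to generate (subset of
#'   `c("eda", "hr", "temp", "acc", "ibi")`).
#' @return Named list of streams; each has `channel`, `start` (UTC epoch
#'   seconds), `rate` (Hz; absent concept for IBI) and `samples` (vector,
#'   3-column matrix for ACC, or an offset/interval data frame for IBI).
#' @export
simulate_physio_day <- function(cohort, participant_id, week_index, day_index,
                                channels = c("eda", "hr", "temp", "acc", "ibi")) {
  stopifnot(inherits(cohort, "sw_cohort"))
  ctx <- day_context(cohort, participant_id, week_index, day_index)
  out <- list()
  for (ch in intersect(c("eda", "hr", "temp", "acc", "ibi"), channels)) {
    gen <- switch(ch, eda = sim_eda_day, hr = sim_hr_day, temp = sim_temp_day,
                  acc = sim_acc_day, ibi = sim_ibi_day)
    out[[ch]] <- withr::with_seed(
      derive_seed(cohort$config$seed, "physio", participant_id, week_index,
                  day_index, ch),
      gen(ctx))
  }
  out
}

# shared per-day state: schedule rows, session span, window indexers and
# the day's motion bursts (drawn under their own seed so every channel
# subset sees the same bursts)
day_context <- function(cohort, participant_id, week_index, day_index) {
  cfg <- cohort$config
  ph <- cohort$effects$physio
  prow <- cohort$participants[
    cohort$participants$participant_id == participant_id, ]
  if (nrow(prow) != 1) stop("unknown participant_id: ", participant_id)
  tr <- cohort$truth[cohort$truth$participant_id == participant_id &
                       cohort$truth$week_index == week_index &
                       cohort$truth$day_index == day_index, ]
  if (nrow(tr) == 0) stop("no scheduled beeps for that participant-day")
  tr <- tr[order(tr$scheduled_time), ]
  w <- cfg$epa_window
  start <- min(tr$scheduled_time) - 900
  span <- max(tr$scheduled_time) - start
  bursts <- withr::with_seed(
    derive_seed(cfg$seed, "physio", participant_id, week_index, day_index,
                "bursts"), {
      n_burst <- stats::rpois(1, ph$burst_rate_per_hour * span / 3600)
      list(t = sort(stats::runif(n_burst, 0, span - 3)),
           dur = stats::runif(n_burst, 1, 3),
           eda_amp = stats::runif(n_burst, ph$burst_eda_amp[1],
                                  ph$burst_eda_amp[2]))
    })
  win_index <- function(rate, n) {
    lapply(tr$scheduled_time, function(bt) {
      ii <- (round((bt - w - start) * rate) + 1):round((bt - start) * rate)
      ii[ii >= 1 & ii <= n]
    })
  }
  list(cfg = cfg, ph = ph, prow = prow, tr = tr, w = w, start = start,
       span = span, bursts = bursts, win_index = win_index)
}

sim_eda_day <- function(ctx) {
  cfg <- ctx$cfg; ph <- ctx$ph; tr <- ctx$tr; prow <- ctx$prow
  rate <- cfg$sample_rates$eda
  n <- round(ctx$span * rate)
  tonic <- prow$tonic_level + smooth_drift(n, rate, ph$tonic_drift_sd)
  train <- numeric(n)
  # ground-truth SCRs inside each pre-beep window
  for (i in seq_len(nrow(tr))) {
    off <- tr$event_offsets[[i]]
    if (length(off)) {
      idx <- round((tr$scheduled_time[i] - ctx$w - ctx$start + off) * rate) + 1
      idx <- pmin(n, pmax(1, idx))
      train[idx] <- train[idx] + tr$event_amps[[i]]
    }
  }
  # background SCRs between windows, at the participant's base rate
  win_lo <- tr$scheduled_time - ctx$w - ctx$start
  win_hi <- tr$scheduled_time - ctx$start
  gaps <- cbind(c(0, win_hi), c(win_lo, ctx$span))
  gaps <- gaps[gaps[, 2] - gaps[, 1] > 1, , drop = FALSE]
  base_rate <- tr$lambda[1] / ctx$w
  for (g in seq_len(nrow(gaps))) {
    len <- gaps[g, 2] - gaps[g, 1]
    k <- stats::rpois(1, base_rate * len)
    if (k) {
      tt <- stats::runif(k, gaps[g, 1], gaps[g, 2])
      amps <- prow$range_amp *
        pmax(ph$scr_amp_floor,
             stats::rnorm(k, ph$scr_amp_mean, ph$scr_amp_jitter))
      idx <- pmin(n, pmax(1, round(tt * rate) + 1))
      train[idx] <- train[idx] + amps
    }
  }
  x <- tonic + conv_bateman(train, rate, cfg_tau_rise(ph), cfg_tau_decay(ph))
  wi <- unlist(ctx$win_index(rate, n), use.names = FALSE)
  x[wi] <- x[wi] + stats::rnorm(length(wi), 0, ph$eda_noise_sd)
  # spike artifacts co-timed with motion bursts
  for (j in seq_along(ctx$bursts$t)) {
    i0 <- round(ctx$bursts$t[j] * rate) + 1
    ii <- i0:min(n, i0 + ph$burst_eda_width - 1)
    x[ii] <- x[ii] + ctx$bursts$eda_amp[j]
  }
  # poor-contact windows: flat, below the quality floor
  for (i in which(!tr$epa_contact)) {
    ii <- (round(win_lo[i] * rate) + 1):round(win_hi[i] * rate)
    ii <- ii[ii >= 1 & ii <= n]
    x[ii] <- pmax(0.001, ph$bad_contact_level +
                    stats::rnorm(length(ii), 0, 0.0003))
  }
  sw_stream("EDA", ctx$start, rate, pmax(x, 0))
}

# SCR shape constants used by the generator (the analysis side has its own
# configurable copies in eda_config)
cfg_tau_rise <- function(ph) ph$bateman_tau_rise %||% 0.75
cfg_tau_decay <- function(ph) ph$bateman_tau_decay %||% 2.0

sim_hr_day <- function(ctx) {
  rate <- ctx$cfg$sample_rates$hr
  n <- round(ctx$span * rate)
  x <- ctx$prow$hr_base + ctx$tr$hr_shift_bpm[1] +
    smooth_drift(n, rate, ctx$ph$hr_drift_sd)
  wi <- unlist(ctx$win_index(rate, n), use.names = FALSE)
  x[wi] <- x[wi] + stats::rnorm(length(wi), 0, ctx$ph$hr_noise_sd)
  sw_stream("HR", ctx$start, rate, pmin(220, pmax(30, x)))
}

sim_temp_day <- function(ctx) {
  rate <- ctx$cfg$sample_rates$temp
  n <- round(ctx$span * rate)
  if (ctx$prow$faulty_temp) {
    x <- rep(0, n)
  } else {
    x <- ctx$prow$temp_base + smooth_drift(n, rate, ctx$ph$temp_drift_sd)
    wi <- unlist(ctx$win_index(rate, n), use.names = FALSE)
    x[wi] <- x[wi] + stats::rnorm(length(wi), 0, ctx$ph$temp_noise_sd)
  }
  sw_stream("TEMP", ctx$start, rate, x)
}

sim_acc_day <- function(ctx) {
  rate <- ctx$cfg$sample_rates$acc
  n <- round(ctx$span * rate)
  ax <- numeric(n); ay <- numeric(n); az <- rep(1, n)
  # wrist noise inside analysis windows only (the watch rests between)
  wi <- unlist(ctx$win_index(rate, n), use.names = FALSE)
  ax[wi] <- stats::rnorm(length(wi), 0, ctx$ph$acc_noise_sd)
  ay[wi] <- stats::rnorm(length(wi), 0, ctx$ph$acc_noise_sd)
  az[wi] <- az[wi] + stats::rnorm(length(wi), 0, ctx$ph$acc_noise_sd)
  for (j in seq_along(ctx$bursts$t)) {
    ii <- (round(ctx$bursts$t[j] * rate) + 1):
      min(n, round((ctx$bursts$t[j] + ctx$bursts$dur[j]) * rate))
    ax[ii] <- ax[ii] + stats::rnorm(length(ii), 0, ctx$ph$burst_acc_sd)
    ay[ii] <- ay[ii] + stats::rnorm(length(ii), 0, ctx$ph$burst_acc_sd)
    az[ii] <- az[ii] + stats::rnorm(length(ii), 0, ctx$ph$burst_acc_sd)
  }
  sw_stream("ACC", ctx$start, rate, cbind(x = ax, y = ay, z = az))
}

sim_ibi_day <- function(ctx) {
  cfg <- ctx$cfg; ph <- ctx$ph; tr <- ctx$tr
  segs <- list()
  for (i in seq_len(nrow(tr))) {
    lo <- tr$scheduled_time[i] - ctx$w - ctx$start
    covered <- 0
    target <- cfg$ibi_coverage * ctx$w
    while (covered < target) {
      dur <- min(stats::rexp(1, 1 / 30) + 5, target - covered + 5)
      s0 <- stats::runif(1, lo, lo + ctx$w - dur)
      nb <- max(1, round(dur / ph$ibi_mean))
      iv <- pmax(0.4, stats::rnorm(nb, ph$ibi_mean, ph$ibi_sd))
      segs[[length(segs) + 1]] <-
        data.frame(offset = s0 + cumsum(iv), interval = iv)
      covered <- covered + sum(iv)
    }
  }
  ib <- do.call(rbind, segs)
  ib <- ib[order(ib$offset), ]
  keep <- c(TRUE, diff(ib$offset) > 0)
  list(channel = "IBI", start = ctx$start, samples = ib[keep, , drop = FALSE])
}

# ACC movement feature per beep without materializing the full-rate day
# stream: reproduces sim_acc_day's draws (same seed, same order) restricted
# to the analysis windows
acc_rmsd_by_beep <- function(cohort, participant_id, week_index, day_index) {
  ctx <- day_context(cohort, participant_id, week_index, day_index)
  rate <- ctx$cfg$sample_rates$acc
  n <- round(ctx$span * rate)
  win <- ctx$win_index(rate, n)
  lens <- lengths(win)
  total <- sum(lens)
  withr::with_seed(
    derive_seed(cohort$config$seed, "physio", participant_id, week_index,
                day_index, "acc"), {
      nx <- stats::rnorm(total, 0, ctx$ph$acc_noise_sd)
      ny <- stats::rnorm(total, 0, ctx$ph$acc_noise_sd)
      nz <- stats::rnorm(total, 0, ctx$ph$acc_noise_sd)
      offs <- c(0, cumsum(lens))      # flat offsets per window
      lo <- vapply(win, function(v) if (length(v)) v[1] else 0L, integer(1))
      hi <- vapply(win, function(v) if (length(v)) v[length(v)] else -1L,
                   integer(1))
      # burst noise overlapping a window (same draw order as sim_acc_day);
      # windows are contiguous index ranges, so overlap is arithmetic
      for (j in seq_along(ctx$bursts$t)) {
        b_lo <- round(ctx$bursts$t[j] * rate) + 1
        b_hi <- min(n, round((ctx$bursts$t[j] + ctx$bursts$dur[j]) * rate))
        len <- b_hi - b_lo + 1
        bx <- stats::rnorm(len, 0, ctx$ph$burst_acc_sd)
        by <- stats::rnorm(len, 0, ctx$ph$burst_acc_sd)
        bz <- stats::rnorm(len, 0, ctx$ph$burst_acc_sd)
        for (k in seq_along(win)) {
          o_lo <- max(b_lo, lo[k]); o_hi <- min(b_hi, hi[k])
          if (o_lo <= o_hi) {
            pos <- (o_lo:o_hi) - lo[k] + offs[k] + 1
            src <- (o_lo:o_hi) - b_lo + 1
            nx[pos] <- nx[pos] + bx[src]
            ny[pos] <- ny[pos] + by[src]
            nz[pos] <- nz[pos] + bz[src]
          }
        }
      }
      vapply(seq_along(win), function(k) {
        if (!lens[k]) return(NA_real_)
        sel <- (offs[k] + 1):offs[k + 1]
        acc_features(cbind(nx[sel], ny[sel], 1 + nz[sel]))$acc_rmsd
      }, numeric(1))
    })
}

# ---- window-segment generation ----------------------------------------------
# Per-beep sensor segments that reproduce exactly the samples the full-day
# streams carry inside the pre-beep windows (identical seeds and draw order;
# the only difference is the truncated SCR convolution lookback, about 1e-7
# microsiemens). This is what the cohort-scale feature extractor uses: it
# avoids materializing half-day streams for every participant-day.

eda_window_streams <- function(ctx) {
  cfg <- ctx$cfg; ph <- ctx$ph; tr <- ctx$tr; prow <- ctx$prow
  rate <- cfg$sample_rates$eda
  n <- round(ctx$span * rate)
  win <- ctx$win_index(rate, n)
  lens <- lengths(win)
  # identical draw sequence to sim_eda_day: drift knots, background events,
  # window noise, poor-contact noise
  kn <- if (ph$tonic_drift_sd > 0 && n >= 4)
    drift_knots(n, rate, ph$tonic_drift_sd) else NULL
  win_lo <- tr$scheduled_time - ctx$w - ctx$start
  win_hi <- tr$scheduled_time - ctx$start
  gaps <- cbind(c(0, win_hi), c(win_lo, ctx$span))
  gaps <- gaps[gaps[, 2] - gaps[, 1] > 1, , drop = FALSE]
  base_rate <- tr$lambda[1] / ctx$w
  bg_t <- numeric(0); bg_a <- numeric(0)
  for (g in seq_len(nrow(gaps))) {
    len <- gaps[g, 2] - gaps[g, 1]
    k <- stats::rpois(1, base_rate * len)
    if (k) {
      tt <- stats::runif(k, gaps[g, 1], gaps[g, 2])
      amps <- prow$range_amp *
        pmax(ph$scr_amp_floor,
             stats::rnorm(k, ph$scr_amp_mean, ph$scr_amp_jitter))
      bg_t <- c(bg_t, tt); bg_a <- c(bg_a, amps)
    }
  }
  noise <- stats::rnorm(sum(lens), 0, ph$eda_noise_sd)
  offs <- c(0, cumsum(lens))
  bad <- which(!tr$epa_contact)
  contact_noise <- lapply(bad, function(i) stats::rnorm(lens[i], 0, 0.0003))
  names(contact_noise) <- as.character(bad)
  bg_idx <- if (length(bg_t)) pmin(n, pmax(1, round(bg_t * rate) + 1))
            else integer(0)
  lookback <- round(30 * rate)   # SCR decay tail < 1e-6 of amplitude
  out <- vector("list", nrow(tr))
  for (k in seq_len(nrow(tr))) {
    if (!lens[k]) next
    lo <- win[[k]][1]; hi <- win[[k]][lens[k]]
    s0 <- max(1, lo - lookback)
    m <- hi - s0 + 1
    tonic <- prow$tonic_level + drift_eval(kn, s0:hi)
    train <- numeric(m)
    off <- tr$event_offsets[[k]]
    if (length(off)) {
      idx <- round((tr$scheduled_time[k] - ctx$w - ctx$start + off) * rate) +
        1 - s0 + 1
      sel <- idx >= 1 & idx <= m
      for (j in which(sel))
        train[idx[j]] <- train[idx[j]] + tr$event_amps[[k]][j]
    }
    near <- which(bg_idx >= s0 & bg_idx <= hi)
    for (j in near) {
      p <- bg_idx[j] - s0 + 1
      train[p] <- train[p] + bg_a[j]
    }
    x <- tonic + conv_bateman(train, rate, cfg_tau_rise(ph), cfg_tau_decay(ph))
    wpos <- (m - lens[k] + 1):m
    x[wpos] <- x[wpos] + noise[(offs[k] + 1):offs[k + 1]]
    for (j in seq_along(ctx$bursts$t)) {
      i0 <- round(ctx$bursts$t[j] * rate) + 1
      ii <- i0:(i0 + ph$burst_eda_width - 1)
      ii <- ii[ii >= s0 & ii <= hi]
      if (length(ii)) x[ii - s0 + 1] <- x[ii - s0 + 1] + ctx$bursts$eda_amp[j]
    }
    if (!tr$epa_contact[k])
      x[wpos] <- pmax(0.001, ph$bad_contact_level +
                        contact_noise[[as.character(k)]])
    out[[k]] <- sw_stream("EDA", ctx$start + (lo - 1) / rate, rate,
                          pmax(x[wpos], 0))
  }
  out
}

level_window_streams <- function(ctx, channel) {
  cfg <- ctx$cfg; ph <- ctx$ph
  rate <- cfg$sample_rates[[tolower(channel)]]
  n <- round(ctx$span * rate)
  win <- ctx$win_index(rate, n)
  lens <- lengths(win)
  out <- vector("list", nrow(ctx$tr))
  if (channel == "TEMP" && ctx$prow$faulty_temp) {
    for (k in seq_len(nrow(ctx$tr)))
      out[[k]] <- sw_stream("TEMP", ctx$start + (win[[k]][1] - 1) / rate,
                            rate, rep(0, lens[k]))
    return(out)
  }
  drift_sd <- if (channel == "HR") ph$hr_drift_sd else ph$temp_drift_sd
  noise_sd <- if (channel == "HR") ph$hr_noise_sd else ph$temp_noise_sd
  base <- if (channel == "HR") ctx$prow$hr_base + ctx$tr$hr_shift_bpm[1]
          else ctx$prow$temp_base
  kn <- if (drift_sd > 0 && n >= 4) drift_knots(n, rate, drift_sd) else NULL
  noise <- stats::rnorm(sum(lens), 0, noise_sd)
  offs <- c(0, cumsum(lens))
  for (k in seq_len(nrow(ctx$tr))) {
    if (!lens[k]) next
    x <- base + drift_eval(kn, win[[k]]) + noise[(offs[k] + 1):offs[k + 1]]
    if (channel == "HR") x <- pmin(220, pmax(30, x))
    out[[k]] <- sw_stream(channel, ctx$start + (win[[k]][1] - 1) / rate,
                          rate, x)
  }
  out
}

# per-beep window streams for the feature extractor (eda/hr/temp segments
# plus precomputed ACC movement)
simulate_window_streams <- function(cohort, participant_id, week_index,
                                    day_index) {
  ctx <- day_context(cohort, participant_id, week_index, day_index)
  seed_ch <- function(ch) derive_seed(cohort$config$seed, "physio",
                                      participant_id, week_index, day_index, ch)
  list(
    tr = ctx$tr,
    eda = withr::with_seed(seed_ch("eda"), eda_window_streams(ctx)),
    hr = withr::with_seed(seed_ch("hr"), level_window_streams(ctx, "HR")),
    temp = withr::with_seed(seed_ch("temp"), level_window_streams(ctx, "TEMP")),
    acc_rmsd = acc_rmsd_by_beep(cohort, participant_id, week_index, day_index)
  )
}
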