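# Per-beep physiological features from the remaining channels, population
# imputation for dead sensors, and the cohort-level extraction loop.

#' Heart-rate window features
#'
#' @param x HR samples (bpm) from the pre-beep window.
#' @return List with `hr_mean`, `hr_min`, `hr_max` (all `NA` on an empty
#'   window).
#' @export
hr_features <- function(x) {
  if (length(x) == 0 || !any(is.finite(x)))
    return(list(hr_mean = NA_real_, hr_min = NA_real_, hr_max = NA_real_))
  list(hr_mean = mean(x), hr_min = min(x), hr_max = max(x))
}

#' Skin-temperature window features
#'
#' The slope is the least-squares linear trend in degrees Celsius per
#' minute. Windows whose median lies outside the physiological 20-42 C
#' range (dead sensor) are returned missing.
#'
#' @param x Temperature samples (C).
#' @param rate Sample rate in Hz.
#' @return List with `temp_mean`, `temp_slope` (C/min) and `temp_ok`.
#' @export
temp_features <- function(x, rate) {
  if (length(x) < 2)
    return(list(temp_mean = NA_real_, temp_slope = NA_real_, temp_ok = FALSE))
  med <- stats::median(x)
  if (!is.finite(med) || med < 20 || med > 42)
    return(list(temp_mean = NA_real_, temp_slope = NA_real_, temp_ok = FALSE))
  tmin <- (seq_along(x) - 1) / rate / 60
  slope <- stats::cov(tmin, x) / stats::var(tmin)
  list(temp_mean = mean(x), temp_slope = slope, temp_ok = TRUE)
}

#' Accelerometer window feature
#'
#' Root-mean-square of the magnitude of the mean-removed 3-axis
#' acceleration: zero for a stationary wrist, growing with movement.
#'
#' @param m Matrix of 3-axis samples (g), one row per sample.
#' @return List with `acc_rmsd` (g).
#' @export
acc_features <- function(m) {
  if (is.null(dim(m)) || nrow(m) == 0)
    return(list(acc_rmsd = NA_real_))
  centred <- sweep(m, 2, colMeans(m))
  list(acc_rmsd = sqrt(mean(rowSums(centred^2))))
}

#' Impute features of dead sensors from the population
#'
#' Participants whose sensor never produced valid values for a feature get
#' every affected value replaced by a draw from
#' `Normal(population mean, population SD)` of the valid donors, with an
#' `imputed_<feature>` flag set, so their remaining data stay usable in the
#' statistical models.
#'
#' @param features Per-beep feature table with `participant_id`.
#' @param feature_names Columns to impute (default the temperature
#'   features).
#' @param seed Seed for the imputation draws.
#' @return `features` with missing values imputed and flag columns added.
#' @export
impute_population <- function(features,
                              feature_names = c("temp_mean", "temp_slope"),
                              seed = 1L) {
  for (f in feature_names) {
    flag <- paste0("imputed_", f)
    if (!flag %in% names(features)) features[[flag]] <- FALSE
    valid <- features[[f]][!is.na(features[[f]])]
    miss <- is.na(features[[f]])
    if (!any(miss)) next
    if (length(valid) < 2 ||
        length(unique(features$participant_id[!is.na(features[[f]])])) < 2)
      stop("no valid donors to impute feature '", f, "'")
    mu <- mean(valid)
    sdv <- stats::sd(valid)
    features[[f]][miss] <- withr::with_seed(
      derive_seed(seed, "impute", f),
      stats::rnorm(sum(miss), mu, sdv))
    features[[flag]][miss] <- TRUE
  }
  features
}

# features of one beep given that day's streams
beep_features <- function(streams, beep_time, config) {
  out <- list(scr_count = NA_real_, scr_magnitude = NA_real_,
              scr_auc = NA_real_, tonic_mean = NA_real_,
              hr_mean = NA_real_, hr_min = NA_real_, hr_max = NA_real_,
              temp_mean = NA_real_, temp_slope = NA_real_,
              acc_rmsd = NA_real_,
              eda_ok = FALSE, eda_reason = NA_character_,
              temp_ok = FALSE, eda_coverage = NA_real_)
  w <- config$window
  if (!is.null(streams$eda)) {
    win <- extract_window(streams$eda, beep_time, w, config$coverage_min)
    out$eda_coverage <- win$coverage
    if (win$missing) {
      out$eda_reason <- "insufficient_coverage"
    } else {
      cl <- clean_eda(win$samples, streams$eda$rate, config)
      if (!cl$ok) {
        out$eda_reason <- cl$reason
      } else {
        dec <- decompose_eda(cl$signal, streams$eda$rate, config)
        scr <- scr_features(dec, streams$eda$rate, config)
        out[names(scr)] <- scr
        out$eda_ok <- TRUE
      }
    }
  }
  if (!is.null(streams$hr)) {
    win <- extract_window(streams$hr, beep_time, w, config$coverage_min)
    if (!win$missing) out[c("hr_mean", "hr_min", "hr_max")] <-
        hr_features(win$samples)
  }
  if (!is.null(streams$temp)) {
    win <- extract_window(streams$temp, beep_time, w, config$coverage_min)
    if (!win$missing) {
      tf <- temp_features(win$samples, streams$temp$rate)
      out[c("temp_mean", "temp_slope", "temp_ok")] <- tf
    }
  }
  if (!is.null(streams$acc)) {
    win <- extract_window(streams$acc, beep_time, w, config$coverage_min)
    if (!win$missing) out["acc_rmsd"] <- acc_features(win$samples)
  }
  out
}

#' Extract per-beep physiological features for a whole cohort
#'
#' Runs the full preprocessing path for every scheduled beep: simulates (or
#' reads) each day's sensor session, extracts the 10-minute pre-beep windows,
#' cleans and decomposes EDA, and summarizes every channel. Temperature
#' features of dead sensors are imputed from the population.
#'
#' @param cohort An `sw_cohort`.
#' @param config An [eda_config()]; `window` also governs the non-EDA
#'   channels.
#' @param sessions_dir Optional directory of written sessions (as from
#'   [write_cohort()]); when `NULL` streams are simulated in memory.
#' @param impute Impute dead-sensor temperature features (default `TRUE`).
#' @param beep_ids Optional subset of beeps to extract (for example only the
#'   answered ones); `NULL` extracts every scheduled beep.
#' @return Tibble with one row per scheduled beep: identifiers, the ten
#'   features, quality flags and an `epa_valid` flag (usable EDA and
#'   complete companion features).
#' @export
extract_epa_features <- function(cohort, config = eda_config(),
                                 sessions_dir = NULL, impute = TRUE,
                                 beep_ids = NULL) {
  stopifnot(inherits(cohort, "sw_cohort"))
  truth <- cohort$truth
  if (!is.null(beep_ids)) truth <- truth[truth$beep_id %in% beep_ids, ]
  days <- unique(truth[, c("participant_id", "week_index", "day_index")])
  rows <- vector("list", nrow(days))
  for (i in seq_len(nrow(days))) {
    d <- days[i, ]
    if (is.null(sessions_dir)) {
      # window-segment generation: identical samples to the full-day
      # streams inside the windows, without materializing half-day vectors
      ws <- simulate_window_streams(cohort, d$participant_id, d$week_index,
                                    d$day_index)
      tr <- ws$tr
      want <- if (is.null(beep_ids)) seq_len(nrow(tr))
              else which(tr$beep_id %in% beep_ids)
      feats <- lapply(want, function(k)
        beep_features(list(eda = ws$eda[[k]], hr = ws$hr[[k]],
                           temp = ws$temp[[k]]),
                      tr$scheduled_time[k], config))
      for (j in seq_along(want)) feats[[j]]$acc_rmsd <- ws$acc_rmsd[want[j]]
      tr <- tr[want, , drop = FALSE]
    } else {
      streams <- read_e4_session(
        file.path(sessions_dir, d$participant_id,
                  sprintf("w%d_d%d", d$week_index, d$day_index)))
      tr <- cohort$truth[cohort$truth$participant_id == d$participant_id &
                           cohort$truth$week_index == d$week_index &
                           cohort$truth$day_index == d$day_index, ]
      tr <- tr[order(tr$scheduled_time), ]
      feats <- lapply(tr$scheduled_time, function(bt)
        beep_features(streams, bt, config))
    }
    tb <- dplyr::bind_rows(lapply(feats, tibble::as_tibble))
    tb <- dplyr::bind_cols(
      tibble::tibble(participant_id = tr$participant_id,
                     beep_id = tr$beep_id), tb)
    rows[[i]] <- tb
  }
  out <- dplyr::bind_rows(rows)
  if (impute) out <- impute_population(out, seed = cohort$config$seed)
  out$epa_valid <- out$eda_ok & !is.na(out$hr_mean) &
    !is.na(out$temp_mean) & !is.na(out$acc_rmsd)
  out
}
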