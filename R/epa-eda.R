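# Electrodermal signal processing: windowing, quality checks, despiking,
# delta-denoising, elliptic low-pass filtering, Bateman deconvolution into
# tonic and phasic components, and SCR feature extraction.

#' EDA processing configuration
#'
#' @param quality_floor Minimum acceptable skin-conductance level in
#'   microsiemens; windows whose median falls below it are marked missing
#'   (default 0.01).
#' @param denoise_delta Largest sample-to-sample change (uS) tolerated
#'   outside genuine SCR rises (default 0.02); faster transient excursions
#'   are interpolated away.
#' @param filter_band Low-pass transition band in Hz: the filter cutoff is
#'   the band midpoint (default `c(0.8, 1.1)`, so 0.95 Hz on the 4 Hz
#'   stream).
#' @param filter_order,filter_ripple_db,filter_atten_db Elliptic filter
#'   design: order, passband ripple (dB) and stopband attenuation (dB),
#'   applied forward-backward for zero phase.
#' @param bateman_tau_rise,bateman_tau_decay Bateman kernel time constants
#'   in seconds.
#' @param scr_amp_threshold Minimum peak prominence (uS) for an SCR to be
#'   counted (default 0.01).
#' @param window Feature window length in seconds (default 600).
#' @param coverage_min Minimum fraction of the window that must be recorded
#'   (default 0.5).
#' @param despike_window Rolling-median window in seconds for despiking
#'   (default 1.25).
#' @param despike_mad_mult Multiple of the residual MAD beyond which a
#'   sample is treated as a spike (default 5).
#' @param deconv_reg Wiener regularization of the Bateman deconvolution, as
#'   a fraction of the kernel's peak spectral magnitude (default 0.025).
#' @return List of class `sw_eda_config`.
#' @export
eda_config <- function(quality_floor = 0.01, denoise_delta = 0.02,
                       filter_band = c(0.8, 1.1), filter_order = 4,
                       filter_ripple_db = 0.1, filter_atten_db = 40,
                       bateman_tau_rise = 0.75, bateman_tau_decay = 2.0,
                       scr_amp_threshold = 0.01, window = 600,
                       coverage_min = 0.5, despike_window = 1.25,
                       despike_mad_mult = 5, deconv_reg = 0.025) {
  if (!(bateman_tau_rise > 0 && bateman_tau_decay > bateman_tau_rise))
    stop_config("bateman_tau_rise", "requires 0 < tau_rise < tau_decay")
  check_pos(quality_floor, "quality_floor")
  if (length(filter_band) != 2 || filter_band[1] >= filter_band[2])
    stop_config("filter_band", "must be (low, high) with low < high")
  structure(list(
    quality_floor = quality_floor, denoise_delta = denoise_delta,
    filter_band = filter_band, filter_order = filter_order,
    filter_ripple_db = filter_ripple_db, filter_atten_db = filter_atten_db,
    bateman_tau_rise = bateman_tau_rise, bateman_tau_decay = bateman_tau_decay,
    scr_amp_threshold = scr_amp_threshold, window = window,
    coverage_min = coverage_min, despike_window = despike_window,
    despike_mad_mult = despike_mad_mult, deconv_reg = deconv_reg),
    class = "sw_eda_config")
}

#' Extract the pre-beep window from a sensor stream
#'
#' Returns the samples in the half-open interval
#' `[beep_time - window, beep_time)` and records the coverage fraction.
#' Features are therefore causal: they depend only on samples strictly
#' before the beep.
#'
#' @param stream A stream as produced by [simulate_physio_day()] or
#'   [read_e4_session()].
#' @param beep_time Beep time, UTC epoch seconds.
#' @param window Window length in seconds.
#' @param coverage_min Below this coverage the window is flagged missing.
#' @return List with `samples` (vector or matrix), `coverage` and `missing`.
#' @export
extract_window <- function(stream, beep_time, window = 600,
                           coverage_min = 0.5) {
  rate <- stream$rate
  n <- if (is.matrix(stream$samples)) nrow(stream$samples)
       else length(stream$samples)
  # sample i has timestamp start + (i - 1) / rate
  i_lo <- ceiling((beep_time - window - stream$start) * rate) + 1
  i_hi <- ceiling((beep_time - stream$start) * rate)  # last sample < beep
  sel <- max(1, i_lo):min(n, i_hi)
  if (i_lo > n || i_hi < 1 || length(sel) == 0 || sel[1] > sel[length(sel)])
    sel <- integer(0)
  expected <- round(window * rate)
  coverage <- length(sel) / expected
  samples <- if (is.matrix(stream$samples))
    stream$samples[sel, , drop = FALSE] else stream$samples[sel]
  list(samples = samples, coverage = coverage,
       missing = coverage < coverage_min)
}

# interpolate over flagged indices using the surrounding good samples
interp_over <- function(x, bad) {
  if (!any(bad)) return(x)
  good <- which(!bad)
  if (length(good) < 2) return(x)
  x[bad] <- stats::approx(good, x[good], xout = which(bad), rule = 2)$y
  x
}

despike_eda <- function(x, rate, config) {
  k <- max(3, round(config$despike_window * rate))
  if (k %% 2 == 0) k <- k + 1
  if (length(x) <= k) return(x)
  med <- stats::runmed(x, k, endrule = "median")
  resid <- x - med
  thr <- config$despike_mad_mult * max(stats::mad(resid), 0.01)
  interp_over(x, abs(resid) > thr)
}

# remove transient excursions: a jump larger than delta that returns to its
# pre-jump level within max_width samples is an artifact (a genuine SCR stays
# elevated far longer at these time constants) and is interpolated away
denoise_eda <- function(x, rate, config) {
  delta <- config$denoise_delta
  max_width <- round(2.5 * rate)
  d <- diff(x)
  onsets <- which(abs(d) > delta)
  # only excursions that start from locally level signal: mid-rise samples
  # of a genuine SCR are never onsets
  onsets <- onsets[onsets == 1 | abs(d[pmax(1, onsets - 1)]) <= delta]
  if (!length(onsets)) return(x)
  bad <- rep(FALSE, length(x))
  i <- 1
  while (i <= length(onsets)) {
    o <- onsets[i]
    level <- x[o]
    ret <- o + which(abs(x[(o + 1):min(length(x), o + max_width)] - level)
                     <= delta)
    if (length(ret)) {
      bad[(o + 1):(ret[1] - 1)] <- TRUE
      onsets <- onsets[onsets >= ret[1] | onsets < o]
      i <- which(onsets >= ret[1])[1]
      if (is.na(i)) break
    } else i <- i + 1
  }
  interp_over(x, bad)
}

.filter_cache <- new.env(parent = emptyenv())

lowpass_eda <- function(x, rate, config) {
  w <- mean(config$filter_band) / (rate / 2)
  if (w >= 1) return(x)        # cutoff at/above Nyquist: nothing to remove
  key <- paste(config$filter_order, config$filter_ripple_db,
               config$filter_atten_db, signif(w, 10), sep = "|")
  fil <- .filter_cache[[key]]
  if (is.null(fil)) {
    fil <- signal::ellip(config$filter_order, config$filter_ripple_db,
                         config$filter_atten_db, w)
    .filter_cache[[key]] <- fil
  }
  # detrend with the endpoint ramp so the filter sees ~zero boundaries
  # (suppresses filtfilt edge transients), then restore it
  ramp <- seq(x[1], x[length(x)], length.out = length(x))
  as.numeric(signal::filtfilt(fil, x - ramp)) + ramp
}

#' Clean a windowed EDA signal
#'
#' Applies the preprocessing chain in order: quality floor check (windows
#' whose median skin conductance is below `quality_floor` are unusable),
#' despiking (rolling-median residual test with interpolation), transient
#' denoising (sample-to-sample changes beyond `denoise_delta` that revert
#' within 2.5 s are interpolated; genuine SCR rises stay elevated and are
#' preserved), and a zero-phase elliptic low-pass filter.
#'
#' @param x Numeric EDA samples (uS).
#' @param rate Sample rate in Hz.
#' @param config An [eda_config()].
#' @return List with `signal` (cleaned samples, same length), `ok` and
#'   `reason` (`NA` or `"below_quality_floor"`).
#' @export
clean_eda <- function(x, rate, config = eda_config()) {
  if (length(x) == 0 || stats::median(x) < config$quality_floor)
    return(list(signal = NULL, ok = FALSE, reason = "below_quality_floor"))
  x <- despike_eda(x, rate, config)
  x <- denoise_eda(x, rate, config)
  x <- lowpass_eda(x, rate, config)
  list(signal = x, ok = TRUE, reason = NA_character_)
}

#' Decompose cleaned EDA into tonic and phasic components
#'
#' Deconvolves the signal with the unit-peak Bateman kernel (Wiener-
#' regularized FFT division) to obtain a driver, splits the driver into a
#' slow (tonic) part by a 4 s moving average and a fast (phasic) part, and
#' reconvolves. The returned components satisfy `tonic + phasic = signal`
#' exactly, and `driver` reconvolved with the kernel reproduces the signal up
#' to the small regularization error.
#'
#' @param x Cleaned EDA samples.
#' @param rate Sample rate in Hz.
#' @param config An [eda_config()].
#' @return List with `tonic`, `phasic`, `driver` (all length of `x`) and
#'   `kernel`.
#' @export
decompose_eda <- function(x, rate, config = eda_config()) {
  n <- length(x)
  h <- bateman_kernel(rate, config$bateman_tau_rise, config$bateman_tau_decay)
  # remove the endpoint ramp so the implicit zero padding sees no step
  # (a step deconvolves into a large edge impulse); the ramp is tonic
  baseline <- seq(x[1], x[n], length.out = n)
  x0 <- x - baseline
  nfft <- stats::nextn(n + length(h), 2)
  H <- stats::fft(c(h, rep(0, nfft - length(h))))
  X <- stats::fft(c(x0, rep(0, nfft - n)))
  lam <- (config$deconv_reg * max(Mod(H)))^2
  D <- X * Conj(H) / (Mod(H)^2 + lam)
  driver <- Re(stats::fft(D, inverse = TRUE))[1:n] / nfft
  movavg <- function(v, k) {
    if (k %% 2 == 0) k <- k + 1
    pad <- (k - 1) / 2
    vp <- c(rep(v[1], pad), v, rep(v[n], pad))
    as.numeric(stats::filter(vp, rep(1 / k, k), sides = 2))[(pad + 1):(pad + n)]
  }
  # slow/fast split of the driver: the tonic driver is an 8 s running
  # median (robust: sparse SCR impulses do not leak into it), the fast part
  # is lightly smoothed (kernel rise time) against deconvolution noise
  k_med <- max(5, round(8 * rate))
  if (k_med %% 2 == 0) k_med <- k_med + 1
  tonic_driver <- if (n > k_med)
    stats::runmed(driver, k_med, endrule = "median") else rep(stats::median(driver), n)
  phasic_driver <- movavg(driver - tonic_driver, max(3, round(1.25 * rate)))
  P <- stats::fft(c(phasic_driver, rep(0, nfft - n)))
  phasic <- Re(stats::fft(P * H, inverse = TRUE))[1:n] / nfft
  list(tonic = x - phasic, phasic = phasic, driver = driver,
       baseline = baseline, kernel = h)
}

# local maxima of x with prominence >= min_prom
find_scr_peaks <- function(x, min_prom) {
  n <- length(x)
  if (n < 3) return(integer(0))
  d <- diff(x)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1
  cand <- cand[x[cand] >= min_prom]   # amplitude floor first (cheap)
  keep <- logical(length(cand))
  for (j in seq_along(cand)) {
    i <- cand[j]
    # walk out to the nearest higher ground on each side; prominence is the
    # peak height above the higher of the two bounding valleys
    left <- x[1:i]
    hi_l <- which(left > x[i])
    vmin_l <- if (length(hi_l)) min(left[max(hi_l):i]) else min(left)
    right <- x[i:n]
    hi_r <- which(right > x[i])
    vmin_r <- if (length(hi_r)) min(right[1:min(hi_r)]) else min(right)
    # an SCR must both rise min_prom above its bounding valleys and reach
    # min_prom absolute phasic amplitude (its reported magnitude)
    keep[j] <- (x[i] - max(vmin_l, vmin_r)) >= min_prom && x[i] >= min_prom
  }
  cand[keep]
}

#' SCR features of one decomposed window
#'
#' Counts phasic responses as local maxima of the phasic component with
#' prominence at least `scr_amp_threshold`, and summarizes their mean peak
#' amplitude, the area under the non-negative phasic curve, and the mean
#' tonic level.
#'
#' @param decomp Output of [decompose_eda()].
#' @param rate Sample rate in Hz.
#' @param config An [eda_config()].
#' @return List with `scr_count`, `scr_magnitude` (uS; 0 when no responses),
#'   `scr_auc` (uS s) and `tonic_mean` (uS).
#' @export
scr_features <- function(decomp, rate, config = eda_config()) {
  peaks <- find_scr_peaks(decomp$phasic, config$scr_amp_threshold)
  # a peak within the kernel width of either edge belongs to an event
  # outside the window; edge transients are excluded with it
  guard <- ceiling(2 * rate)
  peaks <- peaks[peaks > guard & peaks <= length(decomp$phasic) - guard]
  list(
    scr_count = length(peaks),
    scr_magnitude = if (length(peaks)) mean(decomp$phasic[peaks]) else 0,
    scr_auc = sum(pmax(decomp$phasic, 0)) / rate,
    tonic_mean = mean(decomp$tonic)
  )
}
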