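# Reading and writing the wrist-device export dialect: one folder per
# recording session with EDA.csv / HR.csv / TEMP.csv / ACC.csv (line 1 = UTC
# start timestamp in seconds, line 2 = sample rate in Hz, then samples; one
# column per axis for ACC) and IBI.csv (line 1 = start timestamp, then
# "offset_seconds,interval_seconds" rows), plus one long-format EMA table.

fmt_num <- function(x, digits = 6) {
  out <- formatC(x, format = "f", digits = digits, drop0trailing = TRUE)
  sub("^-0$", "0", out)
}

write_channel_csv <- function(stream, path, digits = 6) {
  s <- stream$samples
  nc <- if (is.matrix(s)) ncol(s) else 1
  writeLines(c(paste(rep(fmt_num(stream$start, 2), nc), collapse = ","),
               paste(rep(fmt_num(stream$rate, 2), nc), collapse = ",")),
             path)
  df <- if (is.matrix(s)) data.table::as.data.table(round(s, 6))
        else data.table::data.table(v = round(s, 6))
  data.table::fwrite(df, path, append = TRUE, col.names = FALSE)
}

#' Write a synthetic cohort to disk
#'
#' Writes the long-format EMA table (`ema_long.csv`), a ground-truth latent
#' sidecar for testing (`truth_synthetic.csv`, list columns reduced to
#' counts), and one session folder per participant-day with the sensor
#' channels in the device export dialect.
#'
#' @param cohort An `sw_cohort`.
#' @param dir Output directory (created if needed).
#' @param streams Write the per-day sensor folders (can be slow for large
#'   cohorts; the in-memory pipeline never needs them on disk).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, streams = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$ema, file.path(dir, "ema_long.csv"),
                   row.names = FALSE)
  truth <- cohort$truth
  truth$event_offsets <- NULL
  truth$event_amps <- NULL
  utils::write.csv(truth, file.path(dir, "truth_synthetic.csv"),
                   row.names = FALSE)
  if (streams) {
    days <- unique(cohort$truth[, c("participant_id", "week_index", "day_index")])
    for (i in seq_len(nrow(days))) {
      d <- days[i, ]
      sess <- file.path(dir, d$participant_id,
                        sprintf("w%d_d%d", d$week_index, d$day_index))
      dir.create(sess, recursive = TRUE, showWarnings = FALSE)
      st <- simulate_physio_day(cohort, d$participant_id, d$week_index,
                                d$day_index)
      for (ch in c("eda", "hr", "temp", "acc"))
        write_channel_csv(st[[ch]], file.path(sess, paste0(toupper(ch), ".csv")))
      ib <- st$ibi
      writeLines(c(fmt_num(ib$start, 2),
                   paste(fmt_num(ib$samples$offset),
                         fmt_num(ib$samples$interval), sep = ",")),
                 file.path(sess, "IBI.csv"))
    }
  }
  invisible(dir)
}

#' Read one sensor session folder
#'
#' Parses a session folder in the device export dialect back into the stream
#' structures used by the feature extractor.
#'
#' @param path Session folder containing `EDA.csv`, `HR.csv`, `TEMP.csv`,
#'   `ACC.csv` and optionally `IBI.csv`.
#' @return Named list of streams as produced by [simulate_physio_day()].
#' @export
read_e4_session <- function(path) {
  out <- list()
  for (ch in c("eda", "hr", "temp")) {
    f <- file.path(path, paste0(toupper(ch), ".csv"))
    if (!file.exists(f)) next
    hdr <- as.numeric(readLines(f, n = 2))
    v <- data.table::fread(f, skip = 2, header = FALSE)[[1]]
    out[[ch]] <- sw_stream(toupper(ch), hdr[1], hdr[2], v)
  }
  f <- file.path(path, "ACC.csv")
  if (file.exists(f)) {
    hdr <- lapply(readLines(f, n = 2), function(l)
      as.numeric(strsplit(l, ",")[[1]]))
    m <- as.matrix(data.table::fread(f, skip = 2, header = FALSE))
    dimnames(m) <- list(NULL, c("x", "y", "z"))
    out$acc <- sw_stream("ACC", hdr[[1]][1], hdr[[2]][1], m)
  }
  f <- file.path(path, "IBI.csv")
  if (file.exists(f)) {
    lines <- readLines(f)
    m <- do.call(rbind, lapply(strsplit(lines[-1], ","), as.numeric))
    out$ibi <- list(channel = "IBI", start = as.numeric(lines[1]),
                    samples = data.frame(offset = m[, 1], interval = m[, 2]))
  }
  out
}

#' Read a long-format EMA table
#'
#' @param path CSV written by [write_cohort()] (or a real export with the
#'   same columns).
#' @return Tibble of beep records.
#' @export
read_ema_table <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
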