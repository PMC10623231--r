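# EMA scale scoring: compliance filtering, reverse-scoring, rescaling,
# person-centering and the median-split incongruence summary.

#' Flag beeps answered within the response window
#'
#' A beep is compliant when a completion time exists and falls within
#' `window` seconds of the scheduled time. Non-compliant beeps keep their
#' rows but are excluded from all scoring downstream.
#'
#' @param records Beep table with `scheduled_time` and `completed_time`
#'   (UTC epoch seconds; `NA` when never answered).
#' @param window Response window in seconds (default 3600).
#' @return `records` with a logical `compliance_flag` column.
#' @export
filter_compliance <- function(records, window = 3600) {
  if (!is.numeric(window) || window <= 0)
    stop_config("window", "must be a positive duration in seconds")
  records$compliance_flag <- !is.na(records$completed_time) &
    records$completed_time >= records$scheduled_time &
    records$completed_time - records$scheduled_time <= window
  records
}

#' Score EMA scales from raw items
#'
#' Re-inverts reversed items (`v -> 8 - v`), sums the items of each scale,
#' and rescales the sum to `[0, 1]` using the theoretical scale minimum and
#' maximum. A scale with any missing item is missing for that beep (no
#' prorating). Non-compliant beeps (when `compliance_flag` is present) are
#' never scored.
#'
#' @param records Beep table containing the item columns named in
#'   `scale_map`.
#' @param scale_map See [default_scale_map()].
#' @return `records` keys plus, per scale, `<scale>_raw` (item sum) and
#'   `<scale>` (rescaled to 0..1), with `compliance_flag` carried through.
#' @export
score_scales <- function(records, scale_map = default_scale_map()) {
  all_items <- unlist(lapply(scale_map, `[[`, "items"), use.names = FALSE)
  missing_items <- setdiff(all_items, names(records))
  if (length(missing_items))
    stop("unknown item name(s) not present in records: ",
         paste(missing_items, collapse = ", "))
  keys <- intersect(c("participant_id", "beep_id", "week_type", "week_index",
                      "day_index", "beep_index_in_day", "compliance_flag"),
                    names(records))
  out <- records[, keys, drop = FALSE]
  compliant <- if ("compliance_flag" %in% names(records))
    records$compliance_flag else rep(TRUE, nrow(records))
  for (s in names(scale_map)) {
    items <- scale_map[[s]]$items
    k <- length(items)
    v <- as.matrix(records[, items, drop = FALSE])
    bad <- !is.na(v) & (v < 1 | v > 7 | v != round(v))
    if (any(bad)) stop("Likert values outside 1..7 in scale ", s)
    rev_idx <- which(items %in% scale_map[[s]]$reversed)
    for (j in rev_idx) v[, j] <- 8 - v[, j]
    raw <- rowSums(v)                      # NA if any item missing
    raw[!compliant] <- NA_real_
    out[[paste0(s, "_raw")]] <- raw
    out[[s]] <- (raw - k) / (6 * k)
  }
  tibble::as_tibble(out)
}

#' Person-center scored scales
#'
#' Subtracts each participant's mean (over their compliant beeps across both
#' weeks) from every rescaled scale, producing `<scale>_pc` columns.
#' Participants with fewer than two compliant scored beeps are dropped with
#' a warning.
#'
#' @param scores Output of [score_scales()].
#' @param scales Scales to center (default: all in the scale map).
#' @return `scores` with `_pc` columns; dropped participants removed.
#' @export
person_center <- function(scores, scales = ema_scales()) {
  compliant <- if ("compliance_flag" %in% names(scores))
    scores$compliance_flag else rep(TRUE, nrow(scores))
  n_ok <- tapply(compliant & !is.na(scores[[scales[1]]]),
                 scores$participant_id, sum)
  drop_ids <- names(n_ok)[n_ok < 2]
  if (length(drop_ids)) {
    warning("dropping participant(s) with < 2 compliant beeps: ",
            paste(drop_ids, collapse = ", "))
    scores <- scores[!scores$participant_id %in% drop_ids, , drop = FALSE]
  }
  for (s in scales) {
    m <- tapply(scores[[s]], scores$participant_id, mean, na.rm = TRUE)
    scores[[paste0(s, "_pc")]] <- scores[[s]] -
      as.numeric(m[scores$participant_id])
  }
  scores
}

#' Median-split incongruence of self-reported stress with week type
#'
#' Aggregates event, social and activity stress per beep, splits each
#' participant's beeps at their own median aggregate (across both weeks),
#' and counts beeps whose split-side disagrees with the week type: above the
#' median in the control week, or at/below the median in the stress week.
#' Ties go to "not stressed".
#'
#' @param scores Output of [score_scales()] (person-centering not required)
#'   with a `week_type` column.
#' @return List with `pooled` (overall incongruent fraction) and
#'   `by_participant` (tibble of per-participant fractions and beep counts).
#' @export
median_split_incongruence <- function(scores) {
  ok <- (if ("compliance_flag" %in% names(scores)) scores$compliance_flag
         else TRUE) &
    !is.na(scores$event_stress) & !is.na(scores$social_stress) &
    !is.na(scores$activity_stress)
  d <- scores[ok, , drop = FALSE]
  d$aggregate <- d$event_stress + d$social_stress + d$activity_stress
  per <- dplyr::summarise(
    dplyr::group_by(d, .data$participant_id),
    n_beeps = dplyr::n(),
    incongruent = {
      med <- stats::median(.data$aggregate)
      stressed <- .data$aggregate > med
      sum(stressed != (.data$week_type == "stress"))
    },
    .groups = "drop")
  per$fraction <- per$incongruent / per$n_beeps
  list(pooled = sum(per$incongruent) / sum(per$n_beeps),
       by_participant = per)
}
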