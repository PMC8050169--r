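# Accelerometer (activPAL-style) event-log processing: wear-day validity,
# posture/cadence classification, and daily-mean activity summaries.

#' Cadence threshold separating low- from high-intensity stepping
#'
#' Stepping time with a cadence strictly above this value (steps per minute)
#' counts as high-intensity physical activity (HPA); at or below it, as
#' low-intensity physical activity (LPA).
#' @export
CADENCE_THRESHOLD <- 110

#' Daily HPA threshold implied by the 150 min/week activity guideline
#'
#' Physical-activity guidelines recommend at least 150 minutes of
#' high-intensity activity per week; on a per-day basis this is
#' 150 / 7 = 21.43 min/day. Participants at or above the threshold form the
#' "high HPA" stratum.
#' @export
GUIDELINE_HPA_MIN_PER_DAY <- 150 / 7

#' Validate an event-bout table
#'
#' Event bouts are the atoms of activPAL output: contiguous periods in one
#' posture. Required columns: `participant_id`, `day_index` (integer, 1-based
#' wear day), `start_s` (seconds from the start of that day), `duration_s`,
#' `posture` (one of `"sed"`, `"stand"`, `"step"`), `steps`.
#'
#' @param bouts A data frame of event bouts.
#' @return The validated data frame, invisibly usable downstream.
#' @export
validate_bouts <- function(bouts) {
  req <- c("participant_id", "day_index", "start_s", "duration_s", "posture", "steps")
  miss <- setdiff(req, names(bouts))
  if (length(miss)) stop("bouts table missing columns: ", paste(miss, collapse = ", "))
  if (any(bouts$duration_s <= 0)) stop("all bout durations must be > 0")
  if (any(bouts$steps < 0)) stop("steps must be >= 0")
  if (any(bouts$steps > 0 & bouts$posture != "step")) {
    stop("steps must be 0 for non-stepping bouts")
  }
  if (!all(bouts$posture %in% c("sed", "stand", "step"))) {
    stop("posture must be one of 'sed', 'stand', 'step'")
  }
  # non-overlap within participant-day
  sp <- split(bouts, list(bouts$participant_id, bouts$day_index), drop = TRUE)
  for (b in sp) {
    b <- b[order(b$start_s), ]
    if (nrow(b) > 1 && any(b$start_s[-1] < (b$start_s + b$duration_s)[-nrow(b)] - 1e-9)) {
      stop("overlapping bouts for participant ", b$participant_id[1],
           " day ", b$day_index[1])
    }
  }
  invisible(bouts)
}

#' Classify bouts into behaviour classes by posture and step cadence
#'
#' Sedentary (sit/lie) bouts are sedentary time (ST); standing bouts are
#' standing; stepping bouts are split by cadence, computed per bout as
#' steps divided by bout duration in minutes: strictly more than
#' `cadence_threshold` steps/min is HPA, otherwise LPA.
#'
#' @param posture Character vector: `"sed"`, `"stand"` or `"step"`.
#' @param steps Step counts (0 for non-stepping bouts).
#' @param duration_s Bout durations in seconds; must be > 0.
#' @param cadence_threshold Steps/min boundary (default [CADENCE_THRESHOLD]).
#' @return Character vector with values in `"ST"`, `"standing"`, `"LPA"`, `"HPA"`.
#' @examples
#' classify_bout("step", steps = 1200, duration_s = 600) # 120/min -> "HPA"
#' classify_bout("step", steps = 1100, duration_s = 600) # 110/min -> "LPA"
#' @export
classify_bout <- function(posture, steps, duration_s,
                          cadence_threshold = CADENCE_THRESHOLD) {
  if (any(duration_s <= 0)) stop("bout duration must be > 0")
  cadence <- steps / (duration_s / 60)
  out <- character(length(posture))
  out[posture == "sed"] <- "ST"
  out[posture == "stand"] <- "standing"
  stepping <- posture == "step"
  out[stepping] <- ifelse(cadence[stepping] > cadence_threshold, "HPA", "LPA")
  if (any(out == "")) stop("unknown posture value")
  out
}

# Waking minutes per participant-day from the wake-window table
# (columns participant_id, day_index, wake_start_s, wake_end_s; possibly
# several windows per day).
wake_minutes_by_day <- function(wake_windows) {
  if (any(wake_windows$wake_end_s <= wake_windows$wake_start_s)) {
    stop("wake_end_s must be > wake_start_s")
  }
  agg <- stats::aggregate(
    cbind(wake_min = (wake_windows$wake_end_s - wake_windows$wake_start_s) / 60),
    by = list(participant_id = wake_windows$participant_id,
              day_index = wake_windows$day_index),
    FUN = sum
  )
  agg[order(agg$participant_id, agg$day_index), , drop = FALSE]
}

#' Select valid wear days
#'
#' Applies the wear-protocol validity rules: the first wear day is always
#' excluded (device-attachment day); the final wear day is excluded when it
#' provides 14 or fewer waking hours of data; any remaining day is valid
#' if and only if it provides at least `min_wake_h` (default 10) waking
#' hours. Participants with no valid day are flagged as excluded, not
#' errored.
#'
#' @param wake_windows Wake-window table (`participant_id`, `day_index`,
#'   `wake_start_s`, `wake_end_s`).
#' @param min_wake_h Minimum waking hours for a valid day (default 10).
#' @param final_day_max_h Final-day exclusion boundary in waking hours
#'   (default 14; the final day is dropped when waking data <= this value).
#' @param min_valid_days Minimum number of valid days required to retain a
#'   participant (default 1).
#' @return A list with `days`, a data frame (`participant_id`, `day_index`,
#'   `wake_min`, `valid`, `reason`), and `excluded`, the ids of participants
#'   with fewer than `min_valid_days` valid days.
#' @export
select_valid_days <- function(wake_windows, min_wake_h = 10,
                              final_day_max_h = 14, min_valid_days = 1) {
  wm <- wake_minutes_by_day(wake_windows)
  sp <- split(wm, wm$participant_id)
  days <- do.call(rbind, lapply(sp, function(d) {
    d <- d[order(d$day_index), ]
    d$valid <- TRUE
    d$reason <- ""
    first <- d$day_index == min(d$day_index)
    d$valid[first] <- FALSE
    d$reason[first] <- "first_day"
    final <- d$day_index == max(d$day_index)
    if (any(final & !first) && d$wake_min[final & !first] <= final_day_max_h * 60) {
      d$valid[final] <- FALSE
      d$reason[final] <- "final_day_short"
    }
    short <- d$valid & d$wake_min < min_wake_h * 60
    d$valid[short] <- FALSE
    d$reason[short] <- "short_day"
    d
  }))
  rownames(days) <- NULL
  nvalid <- tapply(days$valid, days$participant_id, sum)
  excluded <- names(nvalid)[nvalid < min_valid_days]
  list(days = days, excluded = excluded)
}

# Intersect bouts with the wake windows of their day; steps are prorated by
# the retained fraction of the bout (cadence is unchanged by truncation).
clip_bouts_to_wake <- function(bouts, wake_windows) {
  key_b <- paste(bouts$participant_id, bouts$day_index)
  key_w <- paste(wake_windows$participant_id, wake_windows$day_index)
  out <- vector("list", nrow(wake_windows))
  for (w in seq_len(nrow(wake_windows))) {
    rows <- which(key_b == key_w[w])
    if (!length(rows)) next
    b <- bouts[rows, , drop = FALSE]
    s <- pmax(b$start_s, wake_windows$wake_start_s[w])
    e <- pmin(b$start_s + b$duration_s, wake_windows$wake_end_s[w])
    keep <- e > s
    if (!any(keep)) next
    b <- b[keep, , drop = FALSE]
    frac <- (e[keep] - s[keep]) / b$duration_s
    b$clip_duration_s <- e[keep] - s[keep]
    b$clip_steps <- b$steps * frac
    out[[w]] <- b
  }
  do.call(rbind, out)
}

#' Summarise per-participant daily-mean activity
#'
#' Classifies each bout (within the wake windows of valid days), sums
#' minutes per behaviour class per day, and averages over valid days.
#' Produces, per participant: mean daily sedentary time (ST), standing
#' time, low- and high-intensity physical activity (LPA, HPA), total
#' physical activity (LPA + HPA), waking time, the number of valid days,
#' and the activity-guideline stratum.
#'
#' @param bouts Event-bout table (see [validate_bouts()]).
#' @param wake_windows Wake-window table.
#' @param validity Optional result of [select_valid_days()]; computed from
#'   `wake_windows` when omitted.
#' @param cadence_threshold Steps/min boundary for HPA (default 110).
#' @return A data frame (one row per retained participant) with columns
#'   `participant_id`, `n_valid_days`, `st_min_day`, `standing_min_day`,
#'   `lpa_min_day`, `hpa_min_day`, `total_pa_min_day`, `wake_min_day`,
#'   `hpa_guideline_high`. Participants with no valid day are dropped and
#'   listed in the `"excluded"` attribute.
#' @export
summarize_activity <- function(bouts, wake_windows, validity = NULL,
                               cadence_threshold = CADENCE_THRESHOLD) {
  validate_bouts(bouts)
  if (is.null(validity)) validity <- select_valid_days(wake_windows)
  vd <- validity$days[validity$days$valid, , drop = FALSE]
  if (!nrow(vd)) {
    stop("no valid participant-days in input")
  }
  ww <- merge(wake_windows, vd[, c("participant_id", "day_index")],
              by = c("participant_id", "day_index"))
  clipped <- clip_bouts_to_wake(bouts, ww)
  clipped$class <- classify_bout(clipped$posture, clipped$clip_steps,
                                 clipped$clip_duration_s, cadence_threshold)
  # per participant-day minutes per class
  agg <- stats::aggregate(clipped$clip_duration_s / 60,
                          by = list(participant_id = clipped$participant_id,
                                    day_index = clipped$day_index,
                                    class = clipped$class),
                          FUN = sum)
  names(agg)[4] <- "minutes"
  wide <- stats::reshape(agg, idvar = c("participant_id", "day_index"),
                         timevar = "class", direction = "wide")
  for (cl in c("ST", "standing", "LPA", "HPA")) {
    col <- paste0("minutes.", cl)
    if (!col %in% names(wide)) wide[[col]] <- 0
    wide[[col]][is.na(wide[[col]])] <- 0
  }
  wm <- wake_minutes_by_day(ww)
  wide <- merge(wide, wm, by = c("participant_id", "day_index"))
  per_part <- split(wide, wide$participant_id)
  out <- do.call(rbind, lapply(per_part, function(d) {
    data.frame(
      participant_id = d$participant_id[1],
      n_valid_days = nrow(d),
      st_min_day = mean(d$minutes.ST),
      standing_min_day = mean(d$minutes.standing),
      lpa_min_day = mean(d$minutes.LPA),
      hpa_min_day = mean(d$minutes.HPA),
      total_pa_min_day = mean(d$minutes.LPA + d$minutes.HPA),
      wake_min_day = mean(d$wake_min),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out$hpa_guideline_high <- guideline_stratify(out$hpa_min_day)
  attr(out, "excluded") <- validity$excluded
  out
}

#' Stratify participants by the physical-activity guideline
#'
#' High-HPA stratum: mean HPA of at least 150/7 = 21.43 min/day (150 min per
#' week). The boundary is inclusive.
#'
#' @param hpa_min_day Numeric vector of mean daily HPA minutes.
#' @param threshold Daily threshold (default [GUIDELINE_HPA_MIN_PER_DAY]).
#' @return Logical vector, `TRUE` for the high-HPA stratum.
#' @export
guideline_stratify <- function(hpa_min_day, threshold = GUIDELINE_HPA_MIN_PER_DAY) {
  hpa_min_day >= threshold
}

#' Invert an exposure so that low activity is the risk factor
#'
#' Physical-activity exposures (total PA, LPA, HPA) are multiplied by -1
#' before modelling so that a positive exposure value represents *low*
#' activity; sedentary time is never inverted.
#'
#' @param x Numeric vector.
#' @return `-x`.
#' @export
invert_exposure <- function(x) {
  stopifnot(is.numeric(x))
  -x
}

#' Add inverted physical-activity exposure columns to a summary table
#'
#' @param data Data frame with `total_pa_min_day`, `lpa_min_day`,
#'   `hpa_min_day`.
#' @return `data` with added `total_pa_inv`, `lpa_inv`, `hpa_inv` columns.
#' @export
add_inverted_exposures <- function(data) {
  data$total_pa_inv <- invert_exposure(data$total_pa_min_day)
  data$lpa_inv <- invert_exposure(data$lpa_min_day)
  data$hpa_inv <- invert_exposure(data$hpa_min_day)
  data
}
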