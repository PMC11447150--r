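# Check-in records, night/day interval construction from submission times,
# and the sensor-coverage filter.

#' Domain catalogue for the daily-functioning check-ins
#'
#' Ten domains are analysed against night-time exposure ("morning
#' functioning") and nine against daytime exposure ("evening functioning").
#' Sleep quality is asked only in the morning; daily memory, productivity and
#' social functioning are asked only in the evening check-in but are analysed
#' against both night-time and daytime hypoglycaemia status. All scales run
#' 0-10 with higher scores meaning better functioning.
#'
#' @return A list with `morning_domains` (10 names), `evening_domains`
#'   (9 names), `morning_asked` (the 7 domains scored in the morning
#'   check-in) and `evening_asked` (the 9 scored in the evening check-in).
#' @export
domain_catalogue <- function() {
  shared <- c("energy_level", "overall_mood", "negative_affect",
              "cognitive_function", "fear_hypoglycaemia", "fear_hyperglycaemia")
  evening_only <- c("daily_memory", "productivity", "social_functioning")
  list(
    morning_domains = c("sleep_quality", shared, evening_only),
    evening_domains = c(shared, evening_only),
    morning_asked = c("sleep_quality", shared),
    evening_asked = c(shared, evening_only))
}

.checkin_kinds <- c("morning", "afternoon", "evening")
.scheduled_clock <- c(morning = 7, afternoon = 15, evening = 21)  # hours

#' Read app check-ins from a delimited file
#'
#' One row per submitted check-in. Domain scores are read from one column per
#' domain (missing columns allowed: afternoon check-ins carry no analysed
#' domains). Rows with any score outside 0-10, an unknown check-in kind, or
#' an unparseable submission timestamp are rejected and counted. Submissions
#' outside the response window that opens at the scheduled clock time are
#' rejected unless `enforce_window = FALSE`. When a participant submits the
#' same kind twice on one date, the earliest submission wins and the
#' duplicate is counted.
#'
#' @param path Path to a delimited text file.
#' @param dialect Named list mapping roles `participant`, `kind`, `submitted`,
#'   `prh_reported`, `prh_detection`, `prh_management`, `prh_severe` to
#'   column names; domain score columns are matched by domain name.
#' @param sep Field separator (default `","`).
#' @param window_hours Length of the response window in hours (default 6).
#' @param enforce_window Reject submissions outside the window? Default `TRUE`.
#' @param tz Time zone for timestamps (default `"UTC"`).
#'
#' @return A data frame of check-ins (one row each) with columns
#'   `participant_id`, `kind`, `date` (calendar date of submission),
#'   `submitted`, one column per known domain, `prh_reported`,
#'   `prh_detection`, `prh_management`, `prh_severe`; the load report is
#'   attached as attribute `"load_report"`.
#' @export
read_checkins <- function(path,
                          dialect = list(participant = "participant_id",
                                         kind = "checkin", submitted = "submitted",
                                         prh_reported = "prh_reported",
                                         prh_detection = "prh_detection",
                                         prh_management = "prh_management",
                                         prh_severe = "prh_severe"),
                          sep = ",", window_hours = 6, enforce_window = TRUE,
                          tz = "UTC") {
  if (!file.exists(path)) stop("check-in file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (role in c("participant", "kind", "submitted"))
    if (!dialect[[role]] %in% names(df))
      stop("check-in file is missing mapped column: ", dialect[[role]])
  cat_all <- union(domain_catalogue()$morning_asked,
                   domain_catalogue()$evening_asked)
  domains_present <- intersect(cat_all, names(df))
  out <- data.frame(
    participant_id = as.character(df[[dialect$participant]]),
    kind = tolower(as.character(df[[dialect$kind]])),
    submitted = .parse_times(df[[dialect$submitted]], tz),
    stringsAsFactors = FALSE)
  for (d in domains_present)
    out[[d]] <- suppressWarnings(as.numeric(df[[d]]))
  grab <- function(role, default = NA_character_) {
    col <- dialect[[role]]
    if (!is.null(col) && col %in% names(df)) as.character(df[[col]])
    else rep(default, nrow(df))
  }
  out$prh_reported <- tolower(grab("prh_reported")) %in% c("yes", "true", "1")
  out$prh_detection <- grab("prh_detection")
  out$prh_management <- grab("prh_management")
  out$prh_severe <- tolower(grab("prh_severe")) %in% c("yes", "true", "1")

  bad_kind <- !out$kind %in% .checkin_kinds
  bad_time <- is.na(out$submitted)
  score_mat <- as.matrix(out[domains_present])
  bad_score <- if (length(domains_present))
    apply(score_mat, 1L, function(s) any(!is.na(s) & (s < 0 | s > 10)))
  else rep(FALSE, nrow(out))
  # response window opens at the scheduled clock time on the submission date
  bad_window <- rep(FALSE, nrow(out))
  if (enforce_window) {
    ok <- !bad_kind & !bad_time
    sched <- as.POSIXct(paste0(format(out$submitted[ok], "%Y-%m-%d"), " 00:00:00"),
                        tz = tz) + .scheduled_clock[out$kind[ok]] * 3600
    lag_h <- as.numeric(difftime(out$submitted[ok], sched, units = "hours"))
    bad_window[ok] <- lag_h < 0 | lag_h > window_hours
  }
  drop <- bad_kind | bad_time | bad_score | bad_window
  report <- list(n_rows = nrow(out), n_rejected = sum(drop),
                 reasons = list(unknown_kind = sum(bad_kind),
                                unparseable_timestamp = sum(bad_time),
                                score_out_of_range = sum(bad_score & !bad_kind & !bad_time),
                                outside_window = sum(bad_window)))
  out <- out[!drop, , drop = FALSE]
  out$date <- as.Date(format(out$submitted, "%Y-%m-%d"))
  # duplicate participant/date/kind: earliest submission wins
  out <- out[order(out$participant_id, out$date, out$kind, out$submitted), ,
             drop = FALSE]
  key <- paste(out$participant_id, out$date, out$kind)
  n_dup <- sum(duplicated(key))
  out <- out[!duplicated(key), , drop = FALSE]
  report$reasons$duplicate_checkin <- n_dup
  rownames(out) <- NULL
  attr(out, "load_report") <- report
  out
}

#' Build night-time and daytime exposure intervals from check-ins
#'
#' The submission times of the morning and evening check-ins divide each
#' 24-hour period into a daytime interval (morning submission to evening
#' submission; its person-reported hypoglycaemia, PRH, is read from that
#' evening check-in) and a night-time interval (evening submission to the
#' next day's morning submission; PRH read from that morning check-in).
#' When the boundary check-in at the non-reporting end is missing, its
#' scheduled clock time (07:00 or 21:00) delimits the interval. When the
#' reporting check-in is missing the interval is emitted with
#' `valid = FALSE` and reason `"no reporting check-in"`.
#'
#' @param checkins Check-in data frame from [read_checkins()] (afternoon
#'   check-ins are ignored here).
#' @param tz Time zone for fallback scheduled boundaries (default `"UTC"`).
#'
#' @return A data frame with one row per participant-date-phase:
#'   `participant_id`, `date`, `phase` (`"night"`/`"day"`), `start`, `end`,
#'   `has_reporting_checkin`, `reporting_kind`, `prh_reported`,
#'   `prh_detection`, `prh_management`, `prh_severe`, `valid` (before the
#'   coverage filter) and `reason`. Intervals of one participant never
#'   overlap.
#' @export
build_intervals <- function(checkins, tz = "UTC") {
  ci <- checkins[checkins$kind %in% c("morning", "evening"), , drop = FALSE]
  at_clock <- function(date, hours)
    as.POSIXct(paste0(format(date, "%Y-%m-%d"), " 00:00:00"), tz = tz) + hours * 3600
  res <- list()
  for (pid in unique(ci$participant_id)) {
    p <- ci[ci$participant_id == pid, , drop = FALSE]
    dates <- seq(min(p$date), max(p$date), by = "day")
    find <- function(d, kind) {
      row <- p[p$date == d & p$kind == kind, , drop = FALSE]
      if (nrow(row)) row else NULL
    }
    for (d in seq_along(dates)) {
      day <- dates[d]
      morn <- find(day, "morning")
      eve <- find(day, "evening")
      morn_next <- find(day + 1L, "morning")
      # daytime: morning -> evening, reported by the evening check-in
      day_start <- if (!is.null(morn)) morn$submitted else at_clock(day, 7)
      day_end <- if (!is.null(eve)) eve$submitted else at_clock(day, 21)
      res[[length(res) + 1L]] <- .interval_row(
        pid, day, "day", day_start, day_end, reporting = eve,
        reporting_kind = "evening")
      # night: evening -> next morning, reported by next morning check-in
      night_start <- if (!is.null(eve)) eve$submitted else at_clock(day, 21)
      night_end <- if (!is.null(morn_next)) morn_next$submitted
                   else at_clock(day + 1L, 7)
      # skip the trailing night that ends beyond the last observed date
      if (day == dates[length(dates)] && is.null(morn_next)) next
      res[[length(res) + 1L]] <- .interval_row(
        pid, day, "night", night_start, night_end, reporting = morn_next,
        reporting_kind = "morning")
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

.interval_row <- function(pid, date, phase, start, end, reporting,
                          reporting_kind) {
  has_rep <- !is.null(reporting)
  data.frame(
    participant_id = pid, date = date, phase = phase,
    start = start, end = end,
    has_reporting_checkin = has_rep,
    reporting_kind = reporting_kind,
    prh_reported = if (has_rep) reporting$prh_reported else NA,
    prh_detection = if (has_rep) reporting$prh_detection else NA_character_,
    prh_management = if (has_rep) reporting$prh_management else NA_character_,
    prh_severe = if (has_rep) reporting$prh_severe else NA,
    valid = has_rep && end > start,
    reason = if (!has_rep) "no reporting check-in"
             else if (end <= start) "non-positive duration" else "",
    stringsAsFactors = FALSE)
}

#' Percent of expected sensor slots missing within an interval
#'
#' The expected number of 5-minute slots is `floor(duration / step)`; the
#' percentage missing is computed over the clock-aligned grid slots falling
#' in `[start, end)`. Slots outside the regularised trace's span count as
#' missing.
#'
#' @param start,end Interval boundaries (`POSIXct`), `start < end`.
#' @param trace A regularised [glucose_trace] for the same participant.
#' @return Percent of expected slots missing, in \[0, 100\].
#' @export
sensor_coverage <- function(start, end, trace) {
  stopifnot(isTRUE(trace$regularized))
  step_sec <- trace$nominal_step * 60
  dur <- as.numeric(difftime(end, start, units = "secs"))
  expected <- floor(dur / step_sec)
  if (expected < 1L) stop("interval shorter than one sensor slot; coverage undefined")
  k0 <- ceiling(as.numeric(start) / step_sec)          # first grid tick >= start
  slots <- seq(k0, length.out = expected)
  trace_k <- round(as.numeric(trace$time) / step_sec)
  hit <- match(slots, trace_k)
  present <- !is.na(hit) & !is.na(trace$glucose[hit])
  # integer arithmetic keeps the exclusion boundary (e.g. exactly 30%) exact
  100 * (expected - sum(present)) / expected
}

#' Apply the sensor-coverage filter to built intervals
#'
#' Computes `pct_sensor_missing` for every interval and invalidates those
#' with strictly more than `max_pct_missing` percent of expected sensor slots
#' missing (an interval with exactly the cutoff percentage is retained).
#'
#' @param intervals Interval table from [build_intervals()].
#' @param traces Named list of regularised traces (names = participant ids).
#' @param max_pct_missing Exclusion cutoff in percent (default 30).
#' @return `intervals` with columns `pct_sensor_missing`, updated `valid` and
#'   `reason`.
#' @export
apply_coverage_filter <- function(intervals, traces, max_pct_missing = 30) {
  pct <- vapply(seq_len(nrow(intervals)), function(i) {
    tr <- traces[[intervals$participant_id[i]]]
    if (is.null(tr)) return(100)
    sensor_coverage(intervals$start[i], intervals$end[i], tr)
  }, numeric(1))
  intervals$pct_sensor_missing <- pct
  excl <- pct > max_pct_missing
  intervals$reason[intervals$valid & excl] <- "sensor coverage below threshold"
  intervals$valid <- intervals$valid & !excl
  intervals
}
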