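# Glucose-trace ingestion, grid regularisation, sensor-hypoglycaemia episode
# detection and standard glycaemic summaries.

#' Construct a glucose trace
#'
#' A `glucose_trace` holds one participant's timestamped interstitial glucose
#' series in mmol/l, sampled at a nominal cadence (5 minutes for the blinded
#' study sensor).
#'
#' @param participant_id Opaque participant identifier (length-1 character).
#' @param time `POSIXct` vector of sample timestamps, strictly increasing.
#' @param glucose Numeric vector of glucose readings (mmol/l), finite and
#'   positive, same length as `time`.
#' @param nominal_step Nominal sampling step in minutes (default 5).
#'
#' @return An object of class `glucose_trace`: a list with elements
#'   `participant_id`, `time`, `glucose`, `nominal_step` (minutes) and
#'   `regularized` (logical).
#' @export
glucose_trace <- function(participant_id, time, glucose, nominal_step = 5) {
  stopifnot(length(participant_id) == 1L, inherits(time, "POSIXct"),
            length(time) == length(glucose), nominal_step > 0)
  if (length(time) > 1L && any(diff(as.numeric(time)) <= 0))
    stop("timestamps must be strictly increasing")
  if (any(!is.finite(glucose)) || any(glucose <= 0))
    stop("glucose values must be finite and > 0")
  structure(
    list(participant_id = as.character(participant_id),
         time = time, glucose = as.numeric(glucose),
         nominal_step = nominal_step, regularized = FALSE),
    class = "glucose_trace")
}

#' @exportS3Method base::print
print.glucose_trace <- function(x, ...) {
  cat(sprintf("<glucose_trace> participant %s: %d samples%s\n",
              x$participant_id, length(x$glucose),
              if (isTRUE(x$regularized))
                sprintf(" on %g-min grid (%d missing)",
                        x$nominal_step, sum(is.na(x$glucose)))
              else " (raw)"))
  invisible(x)
}

#' Read glucose traces from a delimited file
#'
#' Reads a long-format CSV/TSV of timestamped glucose readings and splits it
#' into one [glucose_trace] per participant. Rows whose timestamp cannot be
#' parsed or whose glucose is missing or non-positive are dropped and counted
#' in the load report. Each trace is sorted by time; exact duplicate
#' timestamps within a participant keep the first occurrence.
#'
#' @param path Path to a delimited text file.
#' @param dialect Named list mapping the roles `participant`, `time`,
#'   `glucose` to column names in the file.
#' @param sep Field separator (default `","`).
#' @param nominal_step Nominal sampling step in minutes (default 5).
#' @param tz Time zone used to parse timestamps (default `"UTC"`).
#'
#' @return A named list of [glucose_trace] objects, with the load report
#'   attached as attribute `"load_report"` (a list with `n_rows`, `n_kept`,
#'   `n_rejected` and per-reason counts).
#' @export
read_traces <- function(path, dialect = list(participant = "participant_id",
                                             time = "time",
                                             glucose = "glucose"),
                        sep = ",", nominal_step = 5, tz = "UTC") {
  if (!file.exists(path)) stop("trace file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  needed <- unlist(dialect[c("participant", "time", "glucose")])
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("trace file ", path, " is missing mapped column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("empty trace file: ", path)
    out <- list()
    attr(out, "load_report") <- list(n_rows = 0L, n_kept = 0L,
                                     n_rejected = 0L, reasons = list())
    return(out)
  }
  pid <- as.character(df[[dialect$participant]])
  tm <- .parse_times(df[[dialect$time]], tz)
  gl <- suppressWarnings(as.numeric(df[[dialect$glucose]]))
  bad_time <- is.na(tm)
  bad_gluc <- !bad_time & (!is.finite(gl) | gl <= 0)
  keep <- !bad_time & !bad_gluc
  report <- list(n_rows = nrow(df), n_kept = sum(keep),
                 n_rejected = sum(!keep),
                 reasons = list(unparseable_timestamp = sum(bad_time),
                                nonpositive_glucose = sum(bad_gluc)))
  pid <- pid[keep]; tm <- tm[keep]; gl <- gl[keep]
  traces <- lapply(split(seq_along(pid), pid), function(idx) {
    o <- idx[order(tm[idx])]
    o <- o[!duplicated(tm[o])]
    glucose_trace(pid[o[1L]], tm[o], gl[o], nominal_step = nominal_step)
  })
  attr(traces, "load_report") <- report
  traces
}

# Clock-aligned grid index of a timestamp: slot k covers the nominal tick
# at midnight + k*step. Nearest-tick assignment, ties toward the earlier slot.
.grid_index <- function(time, step_sec) {
  t0 <- as.numeric(time)
  k <- floor(t0 / step_sec)
  frac <- t0 - k * step_sec
  # tie (exact half step) goes to the earlier slot
  k + as.integer(frac > step_sec / 2)
}

#' Snap a glucose trace onto its nominal 5-minute grid
#'
#' Assigns every sample to the nearest clock-aligned nominal tick (ties toward
#' the earlier slot). Grid slots between the first and last observed slot that
#' receive no sample within half a step are marked missing (`NA`). Glucose
#' values are never interpolated; gaps are preserved for the downstream
#' sensor-coverage filter. When several samples map to one slot, the
#' temporally closest is kept and the conflict counted.
#'
#' @param trace A [glucose_trace].
#' @return A regularised `glucose_trace`: `time` is the full grid, `glucose`
#'   has `NA` at missing slots, `regularized` is `TRUE`, and the number of
#'   slot conflicts resolved is attached as attribute `"n_conflicts"`.
#' @export
regularize <- function(trace) {
  stopifnot(inherits(trace, "glucose_trace"))
  if (isTRUE(trace$regularized)) return(trace)
  step_sec <- trace$nominal_step * 60
  k <- .grid_index(trace$time, step_sec)
  dist <- abs(as.numeric(trace$time) - k * step_sec)
  # resolve slot conflicts: keep the temporally closest sample
  o <- order(k, dist)
  k <- k[o]; g <- trace$glucose[o]
  dup <- duplicated(k)
  n_conflicts <- sum(dup)
  k <- k[!dup]; g <- g[!dup]
  full <- seq(min(k), max(k))
  gl <- rep(NA_real_, length(full))
  gl[match(k, full)] <- g
  out <- trace
  out$time <- as.POSIXct(full * step_sec, origin = "1970-01-01",
                         tz = attr(trace$time, "tzone") %||% "UTC")
  out$glucose <- gl
  out$regularized <- TRUE
  attr(out, "n_conflicts") <- n_conflicts
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# lenient ISO-8601 parser: unparseable entries become NA instead of erroring
.parse_times <- function(x, tz = "UTC") {
  x <- as.character(x)
  out <- as.POSIXct(strptime(x, "%Y-%m-%dT%H:%M:%OS", tz = tz))
  for (fmt in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")) {
    miss <- is.na(out) & !is.na(x)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = tz))
  }
  out
}

.sdh_subtype_from_nadir <- function(nadir) {
  ifelse(nadir <= 2.2, "SDH_2.2", ifelse(nadir < 3.0, "SDH_3.0", "SDH_3.9"))
}

#' Detect sensor-detected hypoglycaemia (SDH) episodes
#'
#' An SDH episode is a maximal run of consecutive non-missing grid readings
#' strictly below `threshold` whose covered duration (number of readings times
#' the nominal step) is at least `min_duration`. A run ends at the first
#' reading at or above the threshold, or at a sensor gap whose missing
#' coverage exceeds `gap_bridge` minutes (each missing slot carries one
#' nominal step of coverage; long gaps are never bridged). The episode nadir is
#' the minimum glucose in the run and determines the severity subtype:
#' nadir in \[3.0, 3.9) gives `SDH_3.9`, in (2.2, 3.0) gives `SDH_3.0`, and
#' at or below 2.2 gives `SDH_2.2`.
#'
#' @param trace A regularised [glucose_trace] (see [regularize()]).
#' @param threshold Hypoglycaemia threshold in mmol/l (default 3.9).
#' @param min_duration Minimum covered duration in minutes (default 15, i.e.
#'   at least three consecutive 5-minute readings).
#' @param gap_bridge Maximum within-episode sensor gap, in minutes, that does
#'   not break a run (default 10).
#'
#' @return A data frame with one row per episode: `participant_id`, `start`,
#'   `end` (end = last sub-threshold slot + one step), `n_readings`, `nadir`,
#'   `subtype`. Episodes are time-ordered and non-overlapping.
#' @export
detect_sdh_episodes <- function(trace, threshold = 3.9, min_duration = 15,
                                gap_bridge = 10) {
  stopifnot(inherits(trace, "glucose_trace"))
  if (!isTRUE(trace$regularized))
    stop("detect_sdh_episodes() requires a regularised trace; call regularize() first")
  step <- trace$nominal_step
  idx <- which(!is.na(trace$glucose) & trace$glucose < threshold)
  empty <- data.frame(participant_id = character(), start = as.POSIXct(character()),
                      end = as.POSIXct(character()), n_readings = integer(),
                      nadir = numeric(), subtype = character(),
                      stringsAsFactors = FALSE)
  if (!length(idx)) return(empty)
  # break runs where the missing coverage between consecutive sub-threshold
  # readings exceeds gap_bridge (each missing slot carries one nominal step
  # of coverage), or where an at/above-threshold reading intervenes
  gaps <- (diff(idx) - 1L) * step
  intervening <- vapply(seq_len(length(idx) - 1L), function(i) {
    if (idx[i + 1L] - idx[i] < 2L) return(FALSE)
    any(!is.na(trace$glucose[(idx[i] + 1L):(idx[i + 1L] - 1L)]))
  }, logical(1))
  if (length(idx) == 1L) { runs <- list(idx) } else {
    brk <- gaps > gap_bridge | intervening
    grp <- cumsum(c(0L, as.integer(brk)))
    runs <- split(idx, grp)
  }
  rows <- lapply(runs, function(r) {
    if (length(r) * step < min_duration) return(NULL)
    g <- trace$glucose[r]
    nad <- min(g[!is.na(g)])
    data.frame(participant_id = trace$participant_id,
               start = trace$time[r[1L]],
               end = trace$time[r[length(r)]] + step * 60,
               n_readings = length(r[!is.na(trace$glucose[r])]),
               nadir = nad,
               subtype = .sdh_subtype_from_nadir(nad),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percent time in, above and below the glycaemic target range
#'
#' Computes the standard consensus CGM metrics over the non-missing readings
#' of a trace: percent of readings in range (3.9-10 mmol/l inclusive at both
#' boundaries), above range (>10 mmol/l) and below range (<3.9 mmol/l).
#'
#' @param trace A [glucose_trace] (raw or regularised).
#' @return A list with `pct_in_range`, `pct_above`, `pct_below` and
#'   `n_readings`; the three percentages sum to 100.
#' @export
glycaemic_summary <- function(trace) {
  stopifnot(inherits(trace, "glucose_trace"))
  g <- trace$glucose[!is.na(trace$glucose)]
  if (!length(g)) stop("glycaemic_summary() undefined for an all-missing trace")
  list(pct_in_range = 100 * mean(g >= 3.9 & g <= 10),
       pct_above = 100 * mean(g > 10),
       pct_below = 100 * mean(g < 3.9),
       n_readings = length(g))
}

#' Write an episode table to CSV
#'
#' @param episodes Episode data frame as returned by [detect_sdh_episodes()]
#'   (possibly row-bound over participants).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_episode_table <- function(episodes, path) {
  out <- episodes
  out$start <- format(out$start, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  out$end <- format(out$end, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
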