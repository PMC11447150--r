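# Interval classification by person-reported (PRH) and sensor-detected (SDH)
# hypoglycaemia: the four A-D categories, PRH detection/management subtypes,
# and SDH severity subtypes.

#' Classify an interval by PRH and SDH presence
#'
#' The four exposure categories: type A = neither PRH nor SDH (no
#' hypoglycaemia, the reference), type B = SDH only, type C = PRH only,
#' type D = both PRH and SDH.
#'
#' @param prh_present Logical: any person-reported hypoglycaemia in the
#'   interval.
#' @param sdh_present Logical: any qualifying sensor episode in the interval.
#' @return `"A"`, `"B"`, `"C"` or `"D"` (vectorised).
#' @export
classify_category <- function(prh_present, sdh_present) {
  stopifnot(length(prh_present) == length(sdh_present))
  c("A", "B", "C", "D")[1L + 2L * as.integer(prh_present) +
                          as.integer(sdh_present)]
}

# ranking tables for merging multiple PRH reports within one interval;
# higher rank dominates
.detection_rank <- c(symptomatic = 2, asymptomatic = 1)
.management_rank <- c(treated = 3, prevented = 2, other = 1)

.detection_alias <- c(symptoms = "symptomatic", symptomatic = "symptomatic",
                      own_monitoring = "asymptomatic",
                      asymptomatic = "asymptomatic")
.management_alias <- c(treated = "treated", prevented = "prevented",
                       other = "other")

#' Code PRH detection and management subtypes for one interval
#'
#' Each PRH follow-up answer maps to a detection subtype (`symptomatic`:
#' detected via symptoms; `asymptomatic`: detected via the person's own
#' glucose monitoring) and a management subtype (`prevented`, `treated`,
#' `other`). When an interval carries several reports they are merged by an
#' ordered ranking — symptomatic dominates asymptomatic; treated dominates
#' prevented, which dominates other — and the combined label is the cross of
#' the two merged values. Reports flagged as severe hypoglycaemia are dropped
#' before coding.
#'
#' @param detection Character vector of raw detection answers (one per
#'   report; possibly empty).
#' @param management Character vector of raw management answers, same length.
#' @param severe Logical vector flagging adjudicated severe episodes
#'   (dropped); default all `FALSE`.
#' @param ranking Optional override of the merge ranking: a list with
#'   numeric vectors `detection` and `management` (higher wins).
#' @return A list with `prh_detection`, `prh_management`, `prh_combined`
#'   (e.g. `"symptomatic-treated"`), each `"none"` when no non-severe report
#'   exists, and `prh_present` (logical).
#' @export
code_prh_subtypes <- function(detection, management,
                              severe = rep(FALSE, length(detection)),
                              ranking = NULL) {
  stopifnot(length(detection) == length(management),
            length(severe) == length(detection))
  det_rank <- ranking$detection %||% .detection_rank
  man_rank <- ranking$management %||% .management_rank
  keep <- !severe & !is.na(detection) & !is.na(management)
  detection <- detection[keep]; management <- management[keep]
  if (!length(detection))
    return(list(prh_detection = "none", prh_management = "none",
                prh_combined = "none", prh_present = FALSE))
  det <- unname(.detection_alias[tolower(detection)])
  man <- unname(.management_alias[tolower(management)])
  if (any(is.na(det)))
    stop("unmappable PRH detection answer(s): ",
         paste(unique(detection[is.na(det)]), collapse = ", "))
  if (any(is.na(man)))
    stop("unmappable PRH management answer(s): ",
         paste(unique(management[is.na(man)]), collapse = ", "))
  d <- det[which.max(det_rank[det])]
  m <- man[which.max(man_rank[man])]
  list(prh_detection = d, prh_management = m,
       prh_combined = paste(d, m, sep = "-"), prh_present = TRUE)
}

.sdh_severity <- c(none = 0, SDH_3.9 = 1, SDH_3.0 = 2, SDH_2.2 = 3)

#' Assign the SDH severity subtype of an interval
#'
#' Episodes are clipped to the interval boundaries by re-running the episode
#' detector on the regularised readings falling inside `[start, end)`; an
#' episode straddling a boundary therefore counts only through its clipped
#' portion and must still sustain at least `min_duration` minutes within the
#' interval. The subtype is that of the lowest nadir among qualifying
#' episodes (at or below 2.2 dominates below 3.0, which dominates below 3.9).
#'
#' @param start,end Interval boundaries (`POSIXct`).
#' @param trace Regularised [glucose_trace] of the interval's participant.
#' @inheritParams detect_sdh_episodes
#' @return One of `"none"`, `"SDH_3.9"`, `"SDH_3.0"`, `"SDH_2.2"`.
#' @export
assign_sdh_subtype <- function(start, end, trace, threshold = 3.9,
                               min_duration = 15, gap_bridge = 10) {
  stopifnot(isTRUE(trace$regularized))
  inside <- trace$time >= start & trace$time < end
  if (!any(inside)) return("none")
  sub <- trace
  sub$time <- trace$time[inside]
  sub$glucose <- trace$glucose[inside]
  ep <- detect_sdh_episodes(sub, threshold = threshold,
                            min_duration = min_duration,
                            gap_bridge = gap_bridge)
  if (!nrow(ep)) return("none")
  names(.sdh_severity)[1L + max(.sdh_severity[ep$subtype])]
}

#' Classify all valid intervals
#'
#' Joins the interval table to the sensor traces and PRH answers, producing
#' one classified row per interval: SDH subtype from the clipped episodes,
#' PRH subtypes from the reporting check-in's answers (severe episodes
#' dropped), and the A-D category from the two presence flags.
#'
#' @param intervals Interval table from [apply_coverage_filter()].
#' @param traces Named list of regularised traces.
#' @inheritParams detect_sdh_episodes
#' @return `intervals` with columns `sdh_subtype`, `sdh_present`,
#'   `prh_detection`, `prh_management`, `prh_combined`, `prh_present`,
#'   `category` (`NA` for invalid intervals).
#' @export
classify_intervals <- function(intervals, traces, threshold = 3.9,
                               min_duration = 15, gap_bridge = 10) {
  n <- nrow(intervals)
  sdh_subtype <- rep(NA_character_, n)
  prh_det <- prh_man <- prh_comb <- rep(NA_character_, n)
  prh_present <- sdh_present <- rep(NA, n)
  category <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (!intervals$valid[i]) next
    tr <- traces[[intervals$participant_id[i]]]
    sdh_subtype[i] <- assign_sdh_subtype(intervals$start[i], intervals$end[i],
                                         tr, threshold, min_duration, gap_bridge)
    sdh_present[i] <- sdh_subtype[i] != "none"
    rep_i <- if (isTRUE(intervals$prh_reported[i]))
      code_prh_subtypes(intervals$prh_detection[i],
                        intervals$prh_management[i],
                        severe = isTRUE(intervals$prh_severe[i]))
    else list(prh_detection = "none", prh_management = "none",
              prh_combined = "none", prh_present = FALSE)
    prh_det[i] <- rep_i$prh_detection
    prh_man[i] <- rep_i$prh_management
    prh_comb[i] <- rep_i$prh_combined
    prh_present[i] <- rep_i$prh_present
    category[i] <- classify_category(prh_present[i], sdh_present[i])
  }
  intervals$sdh_subtype <- sdh_subtype
  intervals$sdh_present <- sdh_present
  intervals$prh_detection <- prh_det
  intervals$prh_management <- prh_man
  intervals$prh_combined <- prh_comb
  intervals$prh_present <- prh_present
  intervals$category <- category
  intervals
}
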