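# Seeded synthetic study generator: glucose traces with inserted
# hypoglycaemic excursions, app check-ins with imperfect person-reporting,
# bounded 0-10 domain scores with participant random intercepts and AR(1)
# residuals, baseline covariates, and a ground-truth record for recovery
# testing.

#' Simulation configuration
#'
#' Defaults emulate the parent study's design: two diabetes-type cohorts
#' (274 and 320 participants), 70 days of wear, a 5-minute sensor cadence,
#' morning/evening check-in completion around 86% and 90%, and night/day
#' hypoglycaemia excursion rates tuned so that roughly 72% of nights and 64%
#' of days carry no hypoglycaemia. Excursion depths fall in the three
#' severity strata; a sensor excursion is person-reported with probability
#' `p_detect`, and reports with no sensor excursion occur with probability
#' `p_false_report` per interval.
#'
#' @param n_type1,n_type2 Participants per cohort (defaults 274 and 320).
#' @param n_days Days of wear (default 70).
#' @param step_min Sensor cadence in minutes (default 5).
#' @param night_excursion_rate,day_excursion_rate Expected sensor excursions
#'   per night / per day (defaults 0.28 and 0.31).
#' @param depth_probs Probabilities of the nadir strata
#'   (3.0-3.9, 2.2-3.0, <=2.2 mmol/l); default `c(0.70, 0.22, 0.08)`.
#' @param p_detect Probability that a sensor excursion is person-reported
#'   (default 0.45).
#' @param p_false_report Probability of a person report with no sensor
#'   excursion in the interval (default 0.06 per night, scaled by
#'   `false_report_day_factor` for days).
#' @param false_report_day_factor Multiplier on `p_false_report` for daytime
#'   intervals (default 1.6; perceived episodes are commoner while awake).
#' @param symptomatic_fraction Fraction of reports detected via symptoms
#'   (default 0.7); the rest are detected via the person's own monitoring.
#' @param management_probs Probabilities of treated / prevented / other
#'   (default `c(0.6, 0.3, 0.1)`).
#' @param baseline_range Participant mean glucose range in mmol/l (default
#'   `c(7.5, 9)`).
#' @param glucose_sd Stationary SD of the mean-reverting glucose process
#'   (default 0.9 mmol/l).
#' @param reversion Mean-reversion factor per 5-min step (default 0.92).
#' @param excursion_duration_range Sub-threshold plateau duration range in
#'   minutes (default `c(20, 60)`).
#' @param domain_means Named numeric vector of domain score means on the 0-10
#'   scale (default 7 for every catalogue domain).
#' @param intercept_sd SD of the participant random intercept (default 1.0).
#' @param residual_sd SD of the AR(1) score residual (default 1.5).
#' @param rho AR(1) correlation of score residuals across days (default 0.3).
#' @param effects Category-by-domain score shifts in points: a named list
#'   `list(B = ..., C = ..., D = ...)` where each element is a single number
#'   (applied to all domains) or a named vector by domain. Default
#'   `list(B = -0.05, C = -0.45, D = -0.7)`.
#' @param p_morning,p_evening Check-in completion probabilities (defaults
#'   0.86 and 0.90).
#' @param sensor_dropout Probability that a 5-min slot is missing (gaps are
#'   generated in runs; default 0.03).
#' @param dropout_run_slots Mean length of a sensor gap in slots (default 6).
#' @param seed Integer seed (default 1).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_type1 = 274, n_type2 = 320, n_days = 70,
                       step_min = 5,
                       night_excursion_rate = 0.28, day_excursion_rate = 0.31,
                       depth_probs = c(0.70, 0.22, 0.08),
                       p_detect = 0.45, p_false_report = 0.06,
                       false_report_day_factor = 1.6,
                       symptomatic_fraction = 0.7,
                       management_probs = c(0.6, 0.3, 0.1),
                       baseline_range = c(7.5, 9), glucose_sd = 0.9,
                       reversion = 0.92,
                       excursion_duration_range = c(20, 60),
                       domain_means = NULL, intercept_sd = 1.0,
                       residual_sd = 1.5, rho = 0.3,
                       effects = list(B = -0.05, C = -0.45, D = -0.7),
                       p_morning = 0.86, p_evening = 0.90,
                       sensor_dropout = 0.03, dropout_run_slots = 6,
                       seed = 1L) {
  cat <- domain_catalogue()
  if (is.null(domain_means))
    domain_means <- stats::setNames(rep(7, length(cat$morning_domains)),
                                    cat$morning_domains)
  cfg <- list(n_type1 = n_type1, n_type2 = n_type2, n_days = n_days,
              step_min = step_min,
              night_excursion_rate = night_excursion_rate,
              day_excursion_rate = day_excursion_rate,
              depth_probs = depth_probs, p_detect = p_detect,
              p_false_report = p_false_report,
              false_report_day_factor = false_report_day_factor,
              symptomatic_fraction = symptomatic_fraction,
              management_probs = management_probs,
              baseline_range = baseline_range, glucose_sd = glucose_sd,
              reversion = reversion,
              excursion_duration_range = excursion_duration_range,
              domain_means = domain_means, intercept_sd = intercept_sd,
              residual_sd = residual_sd, rho = rho, effects = effects,
              p_morning = p_morning, p_evening = p_evening,
              sensor_dropout = sensor_dropout,
              dropout_run_slots = dropout_run_slots, seed = as.integer(seed))
  probs <- c(p_detect, p_false_report, symptomatic_fraction, p_morning,
             p_evening, sensor_dropout, depth_probs, management_probs)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(depth_probs) - 1) > 1e-8 || abs(sum(management_probs) - 1) > 1e-8)
    stop("depth_probs and management_probs must each sum to 1")
  if (intercept_sd < 0 || residual_sd < 0) stop("SDs must be >= 0")
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  if (any(domain_means < 0 | domain_means > 10))
    stop("domain score means must lie in [0, 10]")
  class(cfg) <- "sim_config"
  cfg
}

# expands the effects argument into a category x domain matrix in score points
.effect_matrix <- function(effects, domains) {
  m <- matrix(0, nrow = 4, ncol = length(domains),
              dimnames = list(c("A", "B", "C", "D"), domains))
  for (cat in intersect(names(effects), rownames(m))) {
    e <- effects[[cat]]
    if (length(e) == 1L && is.null(names(e))) m[cat, ] <- e
    else m[cat, names(e)] <- e
  }
  m
}

# AR(1) series of length n with stationary sd `sd`
.ar1_noise <- function(n, rho, sd) {
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  if (n > 1) {
    innov_sd <- sd * sqrt(1 - rho^2)
    for (k in 2:n) x[k] <- rho * x[k - 1] + stats::rnorm(1, 0, innov_sd)
  }
  x
}

#' Generate a complete synthetic study
#'
#' Produces, for every participant: a 5-minute glucose trace built from a
#' discretised mean-reverting process around a participant-specific baseline
#' with smooth sub-threshold excursions inserted at configured rates and
#' depths and sensor gaps at the configured dropout rate; morning and
#' evening check-ins with submission-time jitter,
#' missingness, person-reported hypoglycaemia coupled to the inserted
#' excursions through `p_detect` / `p_false_report`, and 0-10 domain scores
#' driven by the interval's true category; and a baseline covariate row.
#' The true category of every interval, the realised effect matrix and the
#' participant intercepts are returned as ground truth.
#'
#' Identical `(config, seed)` yield identical outputs.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, writes `traces.csv`,
#'   `checkins.csv`, `covariates.csv` and `truth.json` there.
#' @return A list with `traces` (data frame: participant_id, time, glucose),
#'   `checkins` (data frame), `covariates` (data frame) and `truth` (list
#'   with `intervals` data frame of true categories, `effect_matrix`,
#'   `participant_intercepts`, `config_digest`).
#' @export
generate_study <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cat <- domain_catalogue()
  domains <- cat$morning_domains
  emat <- .effect_matrix(config$effects, domains)
  n_all <- config$n_type1 + config$n_type2
  ids <- sprintf("P%04d", seq_len(n_all))
  cohort <- rep(c("type1", "type2"), c(config$n_type1, config$n_type2))
  t0 <- as.POSIXct("2021-03-01 00:00:00", tz = "UTC")
  step_sec <- config$step_min * 60
  slots_per_day <- as.integer(24 * 60 / config$step_min)

  covariates <- data.frame(
    participant_id = ids, cohort = cohort,
    age = round(ifelse(cohort == "type1", stats::rnorm(n_all, 44.9, 16.0),
                       stats::rnorm(n_all, 61.9, 10.2))),
    gender = sample(c("male", "female"), n_all, TRUE),
    diabetes_duration = round(pmax(1, ifelse(cohort == "type1",
                                             stats::rnorm(n_all, 23.8, 15.6),
                                             stats::rnorm(n_all, 20.4, 8.9)))),
    impaired_awareness = stats::rbinom(n_all, 1, ifelse(cohort == "type1",
                                                        0.21, 0.27)),
    monitoring = sample(c("fingerprick", "cgm_no_alerts", "cgm_alerts"),
                        n_all, TRUE, c(0.43, 0.53, 0.04)),
    hfs_score = round(pmax(0, stats::rnorm(n_all, 30.6, 21.4))),
    depression = sample(c("none", "mild", "moderate_severe"), n_all, TRUE,
                        c(0.55, 0.26, 0.19)),
    stringsAsFactors = FALSE)
  covariates$age <- pmin(pmax(covariates$age, 18), 90)

  intercepts <- stats::setNames(stats::rnorm(n_all, 0, config$intercept_sd), ids)

  traces <- vector("list", n_all)
  checkins <- list()
  truth_rows <- list()

  for (i in seq_len(n_all)) {
    pid <- ids[i]
    n_slots <- config$n_days * slots_per_day + slots_per_day  # spill into day n+1
    baseline <- stats::runif(1, config$baseline_range[1], config$baseline_range[2])
    g <- .ar1_noise(n_slots, config$reversion, config$glucose_sd) + baseline
    times <- t0 + (seq_len(n_slots) - 1L) * step_sec

    # check-in submission plan: one morning + one evening per day (days are
    # 1..n_days for evenings; mornings span days 1..n_days+1 so the last
    # night interval can close)
    morning_sub <- t0 + (seq_len(config$n_days + 1L) - 1L) * 86400 +
      7 * 3600 + stats::runif(config$n_days + 1L, 5, 110) * 60
    evening_sub <- t0 + (seq_len(config$n_days) - 1L) * 86400 +
      21 * 3600 + stats::runif(config$n_days, 5, 110) * 60
    morning_done <- stats::rbinom(config$n_days + 1L, 1, config$p_morning) == 1
    evening_done <- stats::rbinom(config$n_days, 1, config$p_evening) == 1

    # per-interval truth: excursions and reports
    score_resid <- sapply(domains, function(d)
      .ar1_noise(2 * (config$n_days + 1L), config$rho, config$residual_sd))
    resid_k <- 0

    day_cat <- rep(NA_character_, config$n_days)
    night_cat <- rep(NA_character_, config$n_days)

    for (day in seq_len(config$n_days)) {
      day_t0 <- t0 + (day - 1L) * 86400
      for (phase in c("day", "night")) {
        # nominal windows used for excursion placement (true exposure
        # windows are the submission-to-submission intervals; excursions are
        # placed well inside the nominal windows so the truth is unambiguous)
        if (phase == "day") {
          w_start <- day_t0 + 9 * 3600; w_end <- day_t0 + 20 * 3600
          rate <- config$day_excursion_rate
          p_false <- config$p_false_report * config$false_report_day_factor
        } else {
          w_start <- day_t0 + 23 * 3600; w_end <- day_t0 + 30 * 3600
          rate <- config$night_excursion_rate
          p_false <- config$p_false_report
        }
        n_exc <- stats::rpois(1, rate)
        nadirs <- numeric(0)
        if (n_exc > 0) {
          for (e in seq_len(n_exc)) {
            stratum <- sample.int(3, 1, prob = config$depth_probs)
            nadir <- switch(stratum,
                            stats::runif(1, 3.05, 3.85),
                            stats::runif(1, 2.25, 2.95),
                            stats::runif(1, 1.7, 2.2))
            dur_min <- stats::runif(1, config$excursion_duration_range[1],
                                    config$excursion_duration_range[2])
            dur_slots <- max(3L, as.integer(round(dur_min / config$step_min)))
            start_t <- w_start + stats::runif(1) *
              max(0, as.numeric(difftime(w_end, w_start, units = "secs")) -
                    (dur_slots + 8) * step_sec)
            k0 <- as.integer(floor(as.numeric(difftime(start_t, t0,
                                                       units = "secs")) /
                                     step_sec)) + 1L
            ramp <- 4L  # slots of descent/recovery on each side
            plateau <- k0:(k0 + dur_slots - 1L)
            plateau <- plateau[plateau >= 1 & plateau <= n_slots]
            if (!length(plateau)) next
            g[plateau] <- nadir + stats::runif(length(plateau), 0, 0.04)
            for (r in seq_len(ramp)) {
              frac <- r / (ramp + 1)
              lo <- k0 - r; hi <- max(plateau) + r
              if (lo >= 1) g[lo] <- min(g[lo], nadir + frac * (baseline - nadir))
              if (hi <= n_slots) g[hi] <- min(g[hi], nadir + frac * (baseline - nadir))
            }
            nadirs <- c(nadirs, nadir)
          }
        }
        sdh_true <- length(nadirs) > 0
        reported <- if (sdh_true) stats::runif(1) < config$p_detect
                    else stats::runif(1) < p_false
        true_cat <- classify_category(reported, sdh_true)
        if (phase == "day") day_cat[day] <- true_cat else night_cat[day] <- true_cat
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          participant_id = pid, date = as.Date(day_t0), phase = phase,
          sdh_true = sdh_true, prh_true = reported,
          true_nadir = if (sdh_true) min(nadirs) else NA_real_,
          category = true_cat, stringsAsFactors = FALSE)
      }
    }

    g <- pmax(g, 1.0)  # physiological floor
    # sensor dropout in runs
    miss <- rep(FALSE, n_slots)
    if (config$sensor_dropout > 0) {
      p_start <- config$sensor_dropout / config$dropout_run_slots
      starts <- which(stats::runif(n_slots) < p_start)
      for (s in starts) {
        len <- 1L + stats::rpois(1, config$dropout_run_slots - 1)
        miss[s:min(n_slots, s + len - 1L)] <- TRUE
      }
    }
    traces[[i]] <- data.frame(participant_id = pid,
                              time = times[!miss],
                              glucose = round(g[!miss], 2),
                              stringsAsFactors = FALSE)

    # check-ins with domain scores; morning of day d reports last night
    # (night of day d-1), evening of day d reports that day
    truth_p <- do.call(rbind, truth_rows[(length(truth_rows) -
                                            2L * config$n_days + 1L):
                                           length(truth_rows)])
    for (day in seq_len(config$n_days + 1L)) {
      if (day <= config$n_days && evening_done[day]) {
        cat_day <- day_cat[day]
        resid_k <- resid_k + 1
        scores <- vapply(cat$evening_asked, function(d)
          min(10, max(0, config$domain_means[[d]] + intercepts[[pid]] +
                        emat[cat_day, d] + score_resid[resid_k, d])),
          numeric(1))
        t_day <- truth_p[truth_p$phase == "day" &
                           truth_p$date == as.Date(t0 + (day - 1) * 86400), ]
        checkins[[length(checkins) + 1L]] <- .checkin_row(
          pid, "evening", evening_sub[day], scores, cat$evening_asked,
          domains, t_day$prh_true,
          config, emat)
      }
      if (morning_done[day]) {
        # reports the night starting on day-1
        cat_night <- if (day >= 2) night_cat[day - 1L] else NA_character_
        resid_k <- resid_k + 1
        scores <- if (!is.na(cat_night))
          vapply(cat$morning_asked, function(d)
            min(10, max(0, config$domain_means[[d]] + intercepts[[pid]] +
                          emat[cat_night, d] + score_resid[resid_k, d])),
            numeric(1))
        else
          vapply(cat$morning_asked, function(d)
            min(10, max(0, config$domain_means[[d]] + intercepts[[pid]] +
                          score_resid[resid_k, d])), numeric(1))
        t_night <- if (day >= 2)
          truth_p[truth_p$phase == "night" &
                    truth_p$date == as.Date(t0 + (day - 2) * 86400), ]
        else NULL
        prh <- if (!is.null(t_night) && nrow(t_night)) t_night$prh_true else FALSE
        checkins[[length(checkins) + 1L]] <- .checkin_row(
          pid, "morning", morning_sub[day], scores, cat$morning_asked,
          domains, prh, config, emat)
      }
    }
  }

  checkins_df <- do.call(rbind, checkins)
  traces_df <- do.call(rbind, traces)
  truth_df <- do.call(rbind, truth_rows)
  rownames(checkins_df) <- rownames(traces_df) <- rownames(truth_df) <- NULL
  truth <- list(intervals = truth_df, effect_matrix = emat,
                participant_intercepts = intercepts,
                seed = config$seed)
  out <- list(traces = traces_df, checkins = checkins_df,
              covariates = covariates, truth = truth)
  if (!is.null(out_dir)) write_study(out, out_dir)
  out
}

# one check-in row; PRH follow-up answers are drawn here so that the same
# detection/management distributions apply to true and false reports
.checkin_row <- function(pid, kind, submitted, scores, asked, all_domains,
                         prh, config, emat) {
  row <- data.frame(participant_id = pid, checkin = kind,
                    submitted = format(submitted, "%Y-%m-%dT%H:%M:%S",
                                       tz = "UTC"),
                    stringsAsFactors = FALSE)
  for (d in all_domains)
    row[[d]] <- if (d %in% asked) round(scores[[d]], 1) else NA_real_
  prh <- isTRUE(prh)
  row$prh_reported <- ifelse(prh, "yes", "no")
  if (prh) {
    row$prh_detection <- if (stats::runif(1) < config$symptomatic_fraction)
      "symptomatic" else "asymptomatic"
    row$prh_management <- sample(c("treated", "prevented", "other"), 1,
                                 prob = config$management_probs)
  } else {
    row$prh_detection <- ""
    row$prh_management <- ""
  }
  row$prh_severe <- "no"
  row
}

#' Write a generated study to disk
#'
#' Writes `traces.csv`, `checkins.csv`, `covariates.csv` and `truth.json`
#' with deterministic formatting, so identical `(config, seed)` produce
#' byte-identical files.
#'
#' @param study Output of [generate_study()].
#' @param out_dir Directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_study <- function(study, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(traces = file.path(out_dir, "traces.csv"),
             checkins = file.path(out_dir, "checkins.csv"),
             covariates = file.path(out_dir, "covariates.csv"),
             truth = file.path(out_dir, "truth.json"))
  tr <- study$traces
  tr$time <- format(tr$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(tr, paths["traces"], row.names = FALSE, quote = FALSE)
  utils::write.csv(study$checkins, paths["checkins"], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(study$covariates, paths["covariates"], row.names = FALSE,
                   quote = FALSE)
  truth <- study$truth
  truth$intervals$date <- as.character(truth$intervals$date)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' Summarise the generator's ground truth
#'
#' @param truth The `truth` element of [generate_study()] output.
#' @return A list with `category_frequencies` (proportion of true categories
#'   per phase) and `effect_matrix`.
#' @export
truth_report <- function(truth) {
  tab <- table(truth$intervals$phase, truth$intervals$category)
  freq <- prop.table(tab, margin = 1)
  list(category_frequencies = freq, effect_matrix = truth$effect_matrix)
}

#' Simulate interval-level score data directly
#'
#' A lightweight generator for Monte-Carlo studies of the model stage alone:
#' draws per-participant random intercepts, a category sequence per night,
#' and 0-10 scores (clipped) with AR(1) residuals — no glucose traces or
#' check-in machinery.
#'
#' @param n_participants Number of participants.
#' @param n_intervals Intervals (e.g. nights) per participant.
#' @param category_probs Probabilities of categories A-D per interval
#'   (default the night-time mix `c(0.72, 0.17, 0.032, 0.078)`).
#' @param mean Domain score mean (default 7).
#' @param effects Named vector of score shifts for B, C, D (default all 0).
#' @param intercept_sd,residual_sd,rho As in [sim_config()].
#' @param clip Clip scores to the 0-10 instrument range (default `TRUE`).
#' @return A data frame with `participant_id`, `start` (interval index),
#'   `category` (factor with reference `"A"`), `score`.
#' @export
simulate_interval_scores <- function(n_participants, n_intervals,
                                     category_probs = c(0.72, 0.17, 0.032, 0.078),
                                     mean = 7,
                                     effects = c(B = 0, C = 0, D = 0),
                                     intercept_sd = 1.0, residual_sd = 1.5,
                                     rho = 0.3, clip = TRUE) {
  ids <- sprintf("P%04d", seq_len(n_participants))
  b <- stats::rnorm(n_participants, 0, intercept_sd)
  eff <- c(A = 0, effects)[c("A", "B", "C", "D")]
  rows <- lapply(seq_len(n_participants), function(i) {
    cats <- sample(c("A", "B", "C", "D"), n_intervals, TRUE, category_probs)
    e <- .ar1_noise(n_intervals, rho, residual_sd)
    y <- mean + b[i] + unname(eff[cats]) + e
    if (clip) y <- pmin(10, pmax(0, y))
    data.frame(participant_id = ids[i], start = seq_len(n_intervals),
               category = cats, score = y, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$category <- factor(out$category, levels = c("A", "B", "C", "D"))
  out
}
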