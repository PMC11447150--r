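# In-code fixtures shared across tests.

write_trace_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c("participant_id,time,glucose", rows), path)
  path
}

checkin_header <- paste(c("participant_id,checkin,submitted",
                          "sleep_quality,energy_level,overall_mood",
                          "negative_affect,cognitive_function",
                          "fear_hypoglycaemia,fear_hyperglycaemia",
                          "daily_memory,productivity,social_functioning",
                          "prh_reported,prh_detection,prh_management,prh_severe"),
                        collapse = ",")

# one check-in CSV line with all-7 morning or all-9 evening scores filled
checkin_line <- function(pid, kind, submitted, score = 7,
                         prh = "no", det = "", man = "", severe = "no") {
  sc <- function(x) formatC(x, format = "g")
  vals <- if (kind == "morning")
    c(sc(score), rep(sc(score), 6), "NA", "NA", "NA")
  else if (kind == "evening")
    c("NA", rep(sc(score), 6), rep(sc(score), 3))
  else rep("NA", 10)
  paste(c(pid, kind, submitted, vals, prh, det, man, severe), collapse = ",")
}

write_checkin_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(c(checkin_header, lines), path)
  path
}

# small simulation used by several end-to-end tests
small_sim <- function(seed = 11, ...) {
  sim_config(n_type1 = 8, n_type2 = 8, n_days = 10, seed = seed, ...)
}

# Monte-Carlo study of the model stage: returns per-replicate type-D
# coefficient estimate, p value, CI and intercept
mc_model_study <- function(n_reps, n_participants, n_intervals, effects,
                           seed, mean = 7, ...) {
  out <- matrix(NA_real_, nrow = n_reps, ncol = 5,
                dimnames = list(NULL, c("est", "p", "lo", "hi", "intercept")))
  for (r in seq_len(n_reps)) {
    set.seed(seed + r)
    d <- simulate_interval_scores(n_participants, n_intervals,
                                  effects = effects, mean = mean, ...)
    f <- fit_domain_model(d, outcome = "score", exposure = "category",
                          participant = "participant_id", order_col = "start")
    cf <- f$coefficients
    i <- which(cf$level == "D")
    out[r, ] <- c(cf$estimate[i], cf$p[i], cf$ci_lo[i], cf$ci_hi[i],
                  f$intercept)
  }
  out
}
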