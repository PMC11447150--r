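test_that("read_traces loads, sorts and splits participants, rejecting bad rows", {
  p <- write_trace_csv(c(
    "P1,2021-03-01T00:00:00,5.5",
    "P2,2021-03-01T00:05:00,6.1",
    "P1,2021-03-01T00:10:00,5.0",
    "P1,2021-03-01T00:05:00,5.2",
    "P2,2021-03-01T00:00:00,6.0",
    "P1,2021-03-01T00:15:00,-1",
    "P2,not-a-time,6.2"))
  traces <- read_traces(p)
  expect_named(traces, c("P1", "P2"))
  expect_equal(length(traces$P1$glucose), 3)
  expect_equal(traces$P1$glucose, c(5.5, 5.2, 5.0))
  expect_true(all(diff(traces$P2$time) > 0))
  rep <- attr(traces, "load_report")
  expect_equal(rep$n_rejected, 2)
  expect_equal(rep$reasons$nonpositive_glucose, 1)
  expect_equal(rep$reasons$unparseable_timestamp, 1)
})

test_that("read_traces errors on unmapped columns and warns on empty files", {
  p <- tempfile(fileext = ".csv")
  writeLines("id,when,value", p)
  expect_error(read_traces(p), "missing mapped column")
  writeLines("participant_id,time,glucose", p)
  expect_warning(traces <- read_traces(p), "empty")
  expect_length(traces, 0)
})

test_that("regularize is the identity on exact ticks and flags gap slots", {
  t0 <- as.POSIXct("2021-03-01 06:00:00", tz = "UTC")
  tr <- glucose_trace("P1", t0 + (0:12) * 300, rep(5, 13))
  r <- regularize(tr)
  expect_equal(length(r$glucose), 13)
  expect_equal(sum(is.na(r$glucose)), 0)
  expect_equal(as.numeric(r$time), as.numeric(tr$time))

  # one hour of data with a 20-minute dropout: 4 consecutive missing slots
  keep <- setdiff(1:13, 5:8)
  tr2 <- glucose_trace("P1", (t0 + (0:12) * 300)[keep], rep(5, 9))
  r2 <- regularize(tr2)
  expect_equal(sum(is.na(r2$glucose)), 4)
  expect_true(all(which(is.na(r2$glucose)) == 5:8))
})

test_that("jittered timestamps land on the same slots as the exact grid", {
  set.seed(401)
  t0 <- as.POSIXct("2021-03-01 00:00:00", tz = "UTC")
  for (rep_i in 1:20) {
    n <- 40
    jit <- runif(n, -60, 60)  # within +/- 1 min
    g <- runif(n, 4, 8)
    exact <- regularize(glucose_trace("P1", t0 + (0:(n - 1)) * 300, g))
    jittered <- regularize(glucose_trace("P1", t0 + (0:(n - 1)) * 300 + jit, g))
    # brute-force nearest-slot oracle on the jittered stamps
    oracle_slot <- vapply(as.numeric(t0) + (0:(n - 1)) * 300 + jit,
                          function(s) round(s / 300), numeric(1))
    expect_equal(length(jittered$glucose), length(exact$glucose))
    expect_equal(jittered$glucose, exact$glucose)
    expect_equal(round(as.numeric(jittered$time[!is.na(jittered$glucose)]) / 300),
                 oracle_slot)
  }
})

test_that("slot conflicts keep the temporally closest sample", {
  t0 <- as.POSIXct("2021-03-01 00:00:00", tz = "UTC")
  tr <- glucose_trace("P1", t0 + c(10, 140, 300), c(5, 6, 7))
  r <- regularize(tr)  # 10s and 140s both map to slot 0; 10s is closer
  expect_equal(r$glucose[1], 5)
  expect_equal(attr(r, "n_conflicts"), 1)
})

test_that("episode detection follows the sustained-duration rule", {
  base <- rep(5, 40)
  none <- trace_from_readings(base)
  expect_equal(nrow(detect_sdh_episodes(none)), 0)

  # three consecutive readings below threshold = 15 min covered -> episode
  g <- base; g[10:12] <- 3.5
  ep <- detect_sdh_episodes(trace_from_readings(g))
  expect_equal(nrow(ep), 1)
  expect_equal(ep$subtype, "SDH_3.9")
  expect_equal(ep$nadir, 3.5)
  expect_equal(as.numeric(ep$end - ep$start, units = "mins"), 15)

  # two readings = 10 min covered -> no episode
  g2 <- base; g2[10:11] <- 3.5
  expect_equal(nrow(detect_sdh_episodes(trace_from_readings(g2))), 0)
})

test_that("episode detection requires a regularised trace", {
  t0 <- as.POSIXct("2021-03-01 00:00:00", tz = "UTC")
  raw <- glucose_trace("P1", t0 + (0:9) * 300, rep(3, 10))
  expect_error(detect_sdh_episodes(raw), "regularis")
})

test_that("episodes bridge short gaps but break at long gaps and recoveries", {
  g <- rep(5, 30)
  g[5:7] <- 3.2; g[8] <- NA; g[9:10] <- 3.3          # 10-min gap bridged
  ep <- detect_sdh_episodes(trace_from_readings(g))
  expect_equal(nrow(ep), 1)
  expect_equal(ep$n_readings, 5)

  g2 <- rep(5, 30)
  g2[5:7] <- 3.2; g2[8:10] <- NA; g2[11:13] <- 3.3   # 15-min gap breaks
  ep2 <- detect_sdh_episodes(trace_from_readings(g2))
  expect_equal(nrow(ep2), 2)

  g3 <- rep(5, 30)
  g3[5:7] <- 3.2; g3[8] <- 4.2; g3[9:11] <- 3.3      # recovery breaks
  ep3 <- detect_sdh_episodes(trace_from_readings(g3))
  expect_equal(nrow(ep3), 2)
})

test_that("detector matches the brute-force oracle on random traces", {
  set.seed(402)
  for (rep_i in 1:200) {
    g <- random_readings(sample(10:60, 1))
    got <- episodes_as_slots(detect_sdh_episodes(trace_from_readings(g)))
    want <- oracle_episodes(g)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$nadir, want$nadir)
  }
})

test_that("lowering the threshold never increases the episode count", {
  set.seed(403)
  for (rep_i in 1:100) {
    tr <- trace_from_readings(random_readings(80))
    n39 <- nrow(detect_sdh_episodes(tr, threshold = 3.9))
    n30 <- nrow(detect_sdh_episodes(tr, threshold = 3.0))
    expect_lte(n30, n39)
  }
})

test_that("episode interiors are sub-threshold and flanks are not", {
  set.seed(404)
  t0 <- as.POSIXct("2021-03-01 00:00:00", tz = "UTC")
  for (rep_i in 1:50) {
    g <- random_readings(100)
    tr <- trace_from_readings(g)
    ep <- detect_sdh_episodes(tr)
    slots <- episodes_as_slots(ep)
    for (r in seq_len(nrow(slots))) {
      inside <- g[slots$start[r]:slots$end[r]]
      expect_true(all(inside[!is.na(inside)] < 3.9))
      for (fl in c(slots$start[r] - 1L, slots$end[r] + 1L))
        if (fl >= 1 && fl <= length(g))
          expect_true(is.na(g[fl]) || g[fl] >= 3.9)
    }
  }
})

test_that("glycaemic summary uses inclusive range bounds and sums to 100", {
  tr <- trace_from_readings(rep(5, 20))
  s <- glycaemic_summary(tr)
  expect_equal(c(s$pct_in_range, s$pct_above, s$pct_below), c(100, 0, 0))

  s2 <- glycaemic_summary(trace_from_readings(c(rep(5, 10), rep(11, 10))))
  expect_equal(c(s2$pct_in_range, s2$pct_above, s2$pct_below), c(50, 50, 0))

  # boundary readings count as in range
  s3 <- glycaemic_summary(trace_from_readings(c(3.9, 10, 3.9, 10)))
  expect_equal(s3$pct_in_range, 100)

  set.seed(405)
  for (rep_i in 1:20) {
    s4 <- glycaemic_summary(trace_from_readings(runif(50, 1, 15)))
    expect_equal(s4$pct_in_range + s4$pct_above + s4$pct_below, 100,
                 tolerance = 1e-9)
  }
})

test_that("summary of an all-missing trace errors", {
  tr <- trace_from_readings(c(NA, 5, NA))
  tr$glucose[] <- NA
  expect_error(glycaemic_summary(tr), "all-missing")
})
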