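# Independent oracles used across the suite. These deliberately take a
# different algorithmic route from the package implementation.

# Brute-force episode oracle over a regularised reading vector (NA = missing
# slot). For every candidate start, grows the window while it stays valid
# (endpoints non-missing and below threshold, no at/above-threshold reading
# inside, no internal gap longer than gap_bridge), keeps the largest valid
# window per start, drops windows contained in a larger one, then applies
# the covered-duration filter. Returns a data frame of slot indices.
oracle_episodes <- function(g, threshold = 3.9, min_duration = 15,
                            step = 5, gap_bridge = 10) {
  n <- length(g)
  windows <- list()
  for (i in seq_len(n)) {
    if (is.na(g[i]) || g[i] >= threshold) next
    best_j <- i
    na_run <- 0
    broken <- FALSE
    j <- i
    while (j < n && !broken) {
      j <- j + 1
      if (is.na(g[j])) {
        na_run <- na_run + 1
        if (na_run * step > gap_bridge) broken <- TRUE
      } else if (g[j] >= threshold) {
        broken <- TRUE
      } else {
        na_run <- 0
        best_j <- j
      }
    }
    windows[[length(windows) + 1L]] <- c(i, best_j)
  }
  if (!length(windows)) return(data.frame(start = integer(), end = integer(),
                                          nadir = numeric()))
  w <- do.call(rbind, windows)
  # drop windows strictly contained in another
  maximal <- vapply(seq_len(nrow(w)), function(r) {
    !any(w[, 1] <= w[r, 1] & w[, 2] >= w[r, 2] &
           (w[, 1] < w[r, 1] | w[, 2] > w[r, 2]))
  }, logical(1))
  w <- w[maximal, , drop = FALSE]
  w <- unique(w)
  keep <- vapply(seq_len(nrow(w)), function(r) {
    idx <- w[r, 1]:w[r, 2]
    sum(!is.na(g[idx])) * step >= min_duration
  }, logical(1))
  w <- w[keep, , drop = FALSE]
  if (!nrow(w)) return(data.frame(start = integer(), end = integer(),
                                  nadir = numeric()))
  data.frame(start = as.integer(w[, 1]), end = as.integer(w[, 2]),
             nadir = vapply(seq_len(nrow(w)), function(r)
               min(g[w[r, 1]:w[r, 2]], na.rm = TRUE), numeric(1)))
}

# build a regularised trace from a reading vector (NA = missing slot),
# anchored at midnight UTC
trace_from_readings <- function(g, pid = "T1",
                                t0 = as.POSIXct("2021-03-01 00:00:00",
                                                tz = "UTC")) {
  tr <- glucose_trace(pid, t0 + (seq_along(g) - 1) * 300,
                      ifelse(is.na(g), 5, g))
  tr <- regularize(tr)
  tr$glucose[is.na(g)] <- NA_real_
  tr
}

# episode table -> comparable slot representation relative to the trace grid
episodes_as_slots <- function(ep, t0 = as.POSIXct("2021-03-01 00:00:00",
                                                  tz = "UTC")) {
  if (!nrow(ep)) return(data.frame(start = integer(), end = integer(),
                                   nadir = numeric()))
  data.frame(start = as.integer(round(as.numeric(ep$start - t0, units = "mins") / 5)) + 1L,
             end = as.integer(round(as.numeric(ep$end - t0, units = "mins") / 5)),
             nadir = ep$nadir)
}

# random reading vector: mixture of in-range, low and missing slots
random_readings <- function(n, p_low = 0.2, p_na = 0.1) {
  g <- stats::runif(n, 4.5, 9)
  low <- stats::runif(n) < p_low
  g[low] <- stats::runif(sum(low), 1.8, 3.85)
  g[stats::runif(n) < p_na] <- NA
  g
}
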