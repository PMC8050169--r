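# Independent brute-force oracles and small fixture builders used across
# the test files. These deliberately avoid the package's vectorized code
# paths: the oracle labels every second of the timeline / scans every node
# pair explicitly.

# Per-second labeling of one participant-day: each second of the day is
# labelled with its bout's behaviour class (cadence computed per bout),
# then restricted to the wake window. Integer-second inputs only.
oracle_day_minutes <- function(bouts_day, wake_start_s, wake_end_s,
                               cadence_threshold = 110) {
  lab <- rep(NA_character_, 86400)
  for (r in seq_len(nrow(bouts_day))) {
    b <- bouts_day[r, ]
    cls <- if (b$posture == "sed") "ST"
    else if (b$posture == "stand") "standing"
    else if (b$steps / (b$duration_s / 60) > cadence_threshold) "HPA"
    else "LPA"
    lab[(b$start_s + 1):(b$start_s + b$duration_s)] <- cls
  }
  sel <- lab[(wake_start_s + 1):wake_end_s]
  counts <- table(factor(sel, levels = c("ST", "standing", "LPA", "HPA")))
  as.numeric(counts) / 60
}

# Oracle activity summary: per-second labeling averaged over the supplied
# valid days.
oracle_summary <- function(bouts, wake_windows, valid_days) {
  per_day <- lapply(seq_len(nrow(valid_days)), function(k) {
    pid <- valid_days$participant_id[k]
    day <- valid_days$day_index[k]
    w <- wake_windows[wake_windows$participant_id == pid &
                        wake_windows$day_index == day, ]
    b <- bouts[bouts$participant_id == pid & bouts$day_index == day, ]
    c(oracle_day_minutes(b, w$wake_start_s, w$wake_end_s),
      wake = (w$wake_end_s - w$wake_start_s) / 60)
  })
  m <- do.call(rbind, per_day)
  colnames(m) <- c("st", "standing", "lpa", "hpa", "wake")
  data.frame(participant_id = valid_days$participant_id, m)
}

# Brute-force node degrees: explicit scan over all incident pairs.
brute_force_degrees <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(v) {
    sum(vapply(seq_len(n), function(u) u != v && adj[u, v] > 0, logical(1)))
  }, numeric(1))
}

# Brute-force per-edge occurrence: per-member scan.
brute_force_occurrence <- function(adjs) {
  n <- nrow(adjs[[1]])
  occ <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    for (a in adjs) {
      if (a[i, j] > 0) {
        occ[i, j] <- occ[i, j] + 1L
        occ[j, i] <- occ[i, j]
      }
    }
  }
  occ
}

# Random symmetric binary adjacency with zero diagonal.
random_adj <- function(n, p) {
  m <- matrix(0L, n, n)
  up <- upper.tri(m)
  m[up] <- as.integer(stats::runif(sum(up)) < p)
  m + t(m)
}

# Random connectome wrapping random_adj (counts >= 3 so it is filter-stable).
random_connectome <- function(n, p, icv = 1.5e6) {
  adj <- random_adj(n, p)
  connectome(weight = adj * stats::runif(1, 1e-6, 1e-4),
             streamline_count = adj * 5L,
             icv_mm3 = icv, voxel_volume_mm3 = 8)
}

# Minimal single-participant bout/wake fixture: one day fully partitioned
# into the requested class minutes (used for identity checks).
single_day_fixture <- function(st_min, stand_min, lpa_min, hpa_min,
                               day = 2, pid = "X1", wake_start = 6 * 3600) {
  durs <- c(st_min, stand_min, lpa_min, hpa_min) * 60
  postures <- c("sed", "stand", "step", "step")
  cadences <- c(0, 0, 90, 120)
  keep <- durs > 0
  durs <- durs[keep]; postures <- postures[keep]; cadences <- cadences[keep]
  start <- wake_start + cumsum(c(0, durs[-length(durs)]))
  bouts <- data.frame(
    participant_id = pid, day_index = day, start_s = start,
    duration_s = durs, posture = postures,
    steps = ifelse(postures == "step", cadences * durs / 60, 0)
  )
  wake <- data.frame(participant_id = pid, day_index = day,
                     wake_start_s = wake_start,
                     wake_end_s = wake_start + sum(durs))
  list(bouts = bouts, wake = wake)
}

# Wake-window table for one participant with given waking hours per day.
wake_fixture <- function(hours, pid = "W1") {
  data.frame(participant_id = pid, day_index = seq_along(hours),
             wake_start_s = 6 * 3600,
             wake_end_s = 6 * 3600 + hours * 3600)
}
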