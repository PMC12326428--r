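# Shared fixture builders for the test suite (all generated in code).

# Hand-built behaviour schedule from a list of (label, duration) bouts.
manual_schedule <- function(labels, durations) {
  start <- cumsum(c(0, durations[-length(durations)]))
  out <- data.frame(start = start, end = start + durations, label = labels,
                    stringsAsFactors = FALSE)
  attr(out, "total_duration") <- sum(durations)
  class(out) <- c("behaviour_schedule", "data.frame")
  out
}

# Bundle with a prescribed schedule (deterministic streams unless noise given).
bundle_from_schedule <- function(schedule, seed = 1, noise_sd = 0.05,
                                 fix_dropout_p = 0, include_mask = FALSE,
                                 colony = c(40.539, 141.558),
                                 fly_speed = 10, ...) {
  seeds <- spawn_seeds(seed, 4)
  accel <- synth_acceleration(schedule, noise_sd = noise_sd,
                              seed = seeds[[1]], ...)
  gps <- synth_gps(schedule, colony = colony, fly_speed = fly_speed,
                   fix_dropout_p = fix_dropout_p, seed = seeds[[2]])
  mask <- if (include_mask) synth_mask_ratio(schedule, seed = seeds[[3]])
  structure(list(accel = accel, gps = gps, mask = mask, schedule = schedule,
                 bird_id = "TEST", body_mass = 650, colony = colony),
            class = "sensor_bundle")
}

# Constant-acceleration 1-s window.
constant_window <- function(ax = 0, ay = 0, az = 1, n = 25) {
  data.frame(t = (seq_len(n) - 1) / 25, ax = rep(ax, n), ay = rep(ay, n),
             az = rep(az, n))
}

# Brute-force confusion counts and metrics, independent of the package path.
brute_force_report <- function(pred, truth) {
  classes <- sort(unique(c(pred, truth)))
  out <- list()
  for (cl in classes) {
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(pred)) {
      if (pred[i] == cl && truth[i] == cl) tp <- tp + 1
      if (pred[i] == cl && truth[i] != cl) fp <- fp + 1
      if (pred[i] != cl && truth[i] == cl) fn <- fn + 1
    }
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    out[[cl]] <- c(precision = p, recall = r, f1 = f1)
  }
  out
}

# Exhaustive depth-1 CART oracle: best achievable training accuracy with one
# split (majority-vote leaves), enumerating every feature and midpoint.
depth1_accuracy_oracle <- function(x, y) {
  best <- max(table(y)) / length(y)   # no-split majority baseline
  for (j in seq_len(ncol(x))) {
    v <- sort(unique(x[, j]))
    if (length(v) < 2) next
    for (thr in (v[-1] + v[-length(v)]) / 2) {
      left <- x[, j] <= thr
      acc <- (max(table(factor(y[left]))) + max(table(factor(y[!left])))) /
        length(y)
      best <- max(best, acc)
    }
  }
  best
}
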