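#' Generate an alternating flying / non-flying behaviour schedule
#'
#' Bout durations are exponential (memoryless) with state-specific means,
#' clipped below at 1 s, alternating between the two states. The schedule
#' starts in `first` (a gull resting at the colony by default) and the last
#' bout is truncated so the bouts tile `[0, total_duration]` exactly.
#'
#' @param total_duration Total schedule length in seconds (> 0).
#' @param mean_fly_bout Mean flying-bout duration in seconds (default 300 s,
#'   a plausible scale for gull foraging-flight legs).
#' @param mean_rest_bout Mean non-flying-bout duration in seconds (default
#'   120 s).
#' @param seed Integer seed; identical seeds give identical schedules.
#' @param first State of the first bout.
#' @return A `behaviour_schedule`: data frame with columns `start`, `end`,
#'   `label` (seconds; `label` in `"flying"`/`"non_flying"`), attribute
#'   `total_duration`.
#' @export
#' @examples
#' sch <- generate_schedule(600, seed = 1)
#' sum(sch$end - sch$start)  # 600
generate_schedule <- function(total_duration, mean_fly_bout = 300,
                              mean_rest_bout = 120, seed = NULL,
                              first = c("non_flying", "flying")) {
  if (!is.numeric(total_duration) || total_duration <= 0)
    stop("`total_duration` must be a positive number of seconds")
  if (mean_fly_bout <= 0 || mean_rest_bout <= 0)
    stop("bout duration means must be positive")
  first <- match.arg(first)
  means <- c(flying = mean_fly_bout, non_flying = mean_rest_bout)
  with_seed(seed, {
    labels <- character(0)
    durs <- numeric(0)
    lab <- first
    total <- 0
    while (total < total_duration) {
      d <- max(1, stats::rexp(1, rate = 1 / means[[lab]]))
      d <- min(d, total_duration - total)
      labels <- c(labels, lab)
      durs <- c(durs, d)
      total <- total + d
      lab <- if (lab == "flying") "non_flying" else "flying"
    }
    start <- cumsum(c(0, durs[-length(durs)]))
    out <- data.frame(start = start, end = start + durs, label = labels,
                      stringsAsFactors = FALSE)
    attr(out, "total_duration") <- total_duration
    class(out) <- c("behaviour_schedule", "data.frame")
    out
  })
}

#' Resolve the scheduled behaviour label at given times
#'
#' @param schedule A [generate_schedule()] result.
#' @param t Numeric vector of times in seconds within the schedule.
#' @return Character vector of labels.
#' @export
schedule_label <- function(schedule, t) {
  total <- attr(schedule, "total_duration")
  if (any(t < 0 | t > total)) stop("`t` outside the schedule range")
  idx <- findInterval(t, schedule$start, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  schedule$label[idx]
}

#' Per-second ground-truth labels for a schedule
#'
#' Label of each 1-s window `[k, k+1)`, taken at the window midpoint (a
#' window straddling a bout boundary gets its majority-side label) — the
#' per-second ground truth against which classifier output is scored.
#'
#' @param schedule A [generate_schedule()] result.
#' @return Character vector, one label per whole second.
#' @export
schedule_second_labels <- function(schedule) {
  total <- floor(attr(schedule, "total_duration"))
  schedule_label(schedule, seq_len(total) - 0.5)
}

#' Describe an injectable playback response
#'
#' A response injection adds, after `onset`, extra zero-mean variability that
#' decays exponentially with time constant `decay`, to the named indicator
#' channels. It is the hook through which parameter-recovery tests place a
#' known behavioural response into synthetic streams.
#'
#' @param onset Onset time in seconds since stream start.
#' @param effects Named numeric vector; names among `"s_vedba"`, `"ad_speed"`,
#'   `"ad_mpr"`; values are the initial extra noise SD in channel units
#'   (g, m/s, mask fraction respectively).
#' @param decay Exponential decay time constant in seconds (> 0).
#' @return A `response_injection` object.
#' @export
response_injection <- function(onset, effects, decay = 10) {
  if (!is.numeric(decay) || decay <= 0) stop("`decay` must be > 0")
  if (is.null(names(effects)) ||
      !all(names(effects) %in% c("s_vedba", "ad_speed", "ad_mpr")))
    stop("`effects` must be named with channels s_vedba/ad_speed/ad_mpr")
  structure(list(onset = onset, effects = effects, decay = decay),
            class = "response_injection")
}

# Extra noise SD contributed by injections on `channel` at times `t`.
injection_sd <- function(injections, channel, t) {
  out <- numeric(length(t))
  for (inj in injections) {
    e <- inj$effects[channel]
    if (is.na(e)) next
    on <- t >= inj$onset
    out[on] <- sqrt(out[on]^2 +
                    (e * exp(-(t[on] - inj$onset) / inj$decay))^2)
  }
  out
}

#' Synthesise 25 Hz tri-axial acceleration for a behaviour schedule
#'
#' Flying bouts carry a flapping sinusoid of amplitude `flap_amp` at
#' `flap_freq` on the heave (z) axis on top of 1 g static gravity; non-flying
#' bouts carry gravity only. Gaussian sensor noise of SD `noise_sd` is added
#' to every axis. Body-frame rotation is not modelled: the heave axis holds
#' gravity in both states.
#'
#' @param schedule A [generate_schedule()] result.
#' @param flap_freq Flapping frequency in Hz; must be below the 12.5 Hz
#'   Nyquist limit of the 25 Hz stream. Default 4 Hz (large-gull wingbeat).
#' @param flap_amp Flapping amplitude in g (default 0.5 g).
#' @param noise_sd Sensor noise SD in g (default 0.05 g).
#' @param seed Integer seed.
#' @param injections List of [response_injection()]s; the `s_vedba` effect
#'   adds decaying extra dynamic noise on all three axes.
#' @param fs Sampling rate, fixed at 25 Hz.
#' @return Data frame `t`, `ax`, `ay`, `az` (seconds, g).
#' @export
synth_acceleration <- function(schedule, flap_freq = 4, flap_amp = 0.5,
                               noise_sd = 0.05, seed = NULL,
                               injections = list(), fs = 25) {
  if (flap_freq >= fs / 2)
    stop("`flap_freq` must be below the Nyquist frequency (", fs / 2, " Hz)")
  if (flap_amp < 0 || noise_sd < 0) stop("amplitudes must be non-negative")
  total <- attr(schedule, "total_duration")
  n <- round(total * fs)
  t <- (seq_len(n) - 1L) / fs
  flying <- schedule_label(schedule, t) == "flying"
  with_seed(seed, {
    ax <- stats::rnorm(n, 0, noise_sd)
    ay <- stats::rnorm(n, 0, noise_sd)
    az <- 1 + flap_amp * as.numeric(flying) * sin(2 * pi * flap_freq * t) +
      stats::rnorm(n, 0, noise_sd)
    s <- injection_sd(injections, "s_vedba", t)
    if (any(s > 0)) {
      ax <- ax + stats::rnorm(n, 0, s)
      ay <- ay + stats::rnorm(n, 0, s)
      az <- az + stats::rnorm(n, 0, s)
    }
    data.frame(t = t, ax = ax, ay = ay, az = az)
  })
}

# Destination point on a sphere from (lat, lon) degrees along initial
# bearing (degrees clockwise from north) for distance km. Earth R = 6371 km.
destination_point <- function(lat, lon, bearing, dist_km) {
  R <- 6371.0
  phi1 <- lat * pi / 180
  lam1 <- lon * pi / 180
  th <- bearing * pi / 180
  delta <- dist_km / R
  phi2 <- asin(sin(phi1) * cos(delta) + cos(phi1) * sin(delta) * cos(th))
  lam2 <- lam1 + atan2(sin(th) * sin(delta) * cos(phi1),
                       cos(delta) - sin(phi1) * sin(phi2))
  cbind(lat = phi2 * 180 / pi,
        lon = ((lam2 * 180 / pi + 540) %% 360) - 180)
}

#' Synthesise a 1 Hz GPS stream for a behaviour schedule
#'
#' During non-flying bouts the bird sits at the colony centre with zero
#' ground speed. Each flying bout is an outbound excursion: position
#' integrates from the colony along one uniformly drawn fixed bearing at
#' `fly_speed`; the return leg is not modelled (position pins back to the
#' colony at the next non-flying bout). Each sample independently fails to
#' obtain a 3D fix with probability `fix_dropout_p`.
#'
#' @param schedule A [generate_schedule()] result.
#' @param colony Numeric `c(lat, lon)` of the colony centre in degrees.
#' @param fly_speed Flight ground speed in m/s (default 10 m/s).
#' @param fix_dropout_p Per-sample probability of a failed 3D fix.
#' @param seed Integer seed.
#' @param injections List of [response_injection()]s; the `ad_speed` effect
#'   adds decaying zero-mean jitter to the reported ground speed (clipped at
#'   0) without moving the position.
#' @return Data frame `t`, `lat`, `lon`, `speed`, `fix3d` at 1 Hz.
#' @export
synth_gps <- function(schedule, colony = c(40.539, 141.558), fly_speed = 10,
                      fix_dropout_p = 0.05, seed = NULL,
                      injections = list()) {
  if (fix_dropout_p < 0 || fix_dropout_p > 1)
    stop("`fix_dropout_p` must be in [0, 1]")
  if (fly_speed < 0) stop("`fly_speed` must be >= 0")
  total <- floor(attr(schedule, "total_duration"))
  t <- seq_len(total) - 1
  lab <- schedule_label(schedule, t)
  flying <- lab == "flying"
  with_seed(seed, {
    fly_rows <- which(schedule$label == "flying")
    bearings <- stats::runif(length(fly_rows), 0, 360)
    lat <- rep(colony[1], total)
    lon <- rep(colony[2], total)
    speed <- ifelse(flying, fly_speed, 0)
    bout_idx <- findInterval(t, schedule$start, rightmost.closed = TRUE)
    for (k in seq_along(fly_rows)) {
      r <- fly_rows[k]
      sel <- which(bout_idx == r)
      if (!length(sel)) next
      d_km <- fly_speed * (t[sel] - schedule$start[r]) / 1000
      p <- destination_point(colony[1], colony[2], bearings[k], d_km)
      lat[sel] <- p[, "lat"]
      lon[sel] <- p[, "lon"]
    }
    fix3d <- stats::runif(total) >= fix_dropout_p
    s <- injection_sd(injections, "ad_speed", t)
    if (any(s > 0)) speed <- pmax(0, speed + stats::rnorm(total, 0, s))
    data.frame(t = t, lat = lat, lon = lon, speed = speed, fix3d = fix3d)
  })
}

#' Synthesise a 30 FPS masked-pixel-ratio stream
#'
#' The mask-pixel ratio (fraction of frame pixels covered by the segmented
#' head/neck mask) is a baseline plus Gaussian frame jitter, clipped to
#' `[0, 1]`. Each injection adds extra frame-to-frame variability after its
#' onset, decaying exponentially — the vigilance-spike signature that AD-MPR
#' is designed to pick up.
#'
#' @param schedule A [generate_schedule()] result (sets the stream length).
#' @param base_mpr Baseline mask ratio in `[0, 1]` (default 0.2).
#' @param jitter_sd Frame jitter SD (default 0.02).
#' @param injections List of [response_injection()]s (`ad_mpr` effects).
#' @param seed Integer seed.
#' @param fps Frame rate, fixed at 30 FPS.
#' @return Data frame `t`, `mpr`.
#' @export
synth_mask_ratio <- function(schedule, base_mpr = 0.2, jitter_sd = 0.02,
                             injections = list(), seed = NULL, fps = 30) {
  if (base_mpr < 0 || base_mpr > 1) stop("`base_mpr` must be in [0, 1]")
  if (jitter_sd < 0) stop("`jitter_sd` must be >= 0")
  total <- attr(schedule, "total_duration")
  n <- round(total * fps)
  t <- (seq_len(n) - 1L) / fps
  with_seed(seed, {
    mpr <- base_mpr + stats::rnorm(n, 0, jitter_sd)
    s <- injection_sd(injections, "ad_mpr", t)
    if (any(s > 0)) mpr <- mpr + stats::rnorm(n, 0, s)
    data.frame(t = t, mpr = pmin(1, pmax(0, mpr)))
  })
}

#' Generate a complete synchronized sensor bundle
#'
#' Builds schedule, acceleration, GPS and mask-ratio streams sharing one
#' `t = 0` origin, with per-stream seeds spawned deterministically from
#' `seed`. This is the study-condition generator every simulation-based test
#' in the package runs on.
#'
#' @param total_duration Bundle length in seconds.
#' @param bird_id Identifier string.
#' @param body_mass Body mass in grams.
#' @param colony `c(lat, lon)` colony centre.
#' @param seed Master seed for the bundle.
#' @param injections List of [response_injection()]s routed to all streams.
#' @param include_mask Set `FALSE` to skip the (large) 30 FPS mask stream.
#' @param mean_fly_bout,mean_rest_bout,first Passed to [generate_schedule()].
#' @param flap_freq,flap_amp,noise_sd Passed to [synth_acceleration()].
#' @param fly_speed,fix_dropout_p Passed to [synth_gps()].
#' @param base_mpr,jitter_sd Passed to [synth_mask_ratio()].
#' @return A `sensor_bundle`: list with `accel`, `gps`, `mask` (or `NULL`),
#'   `schedule`, `bird_id`, `body_mass`, `colony`.
#' @export
#' @examples
#' b <- synth_bundle(120, seed = 1, include_mask = FALSE)
#' nrow(b$accel)  # 120 * 25
synth_bundle <- function(total_duration = 1800, bird_id = "SIM00",
                         body_mass = 650, colony = c(40.539, 141.558),
                         seed = NULL, injections = list(),
                         include_mask = TRUE,
                         mean_fly_bout = 300, mean_rest_bout = 120,
                         first = "non_flying",
                         flap_freq = 4, flap_amp = 0.5, noise_sd = 0.05,
                         fly_speed = 10, fix_dropout_p = 0.05,
                         base_mpr = 0.2, jitter_sd = 0.02) {
  seeds <- spawn_seeds(seed, 4)
  schedule <- generate_schedule(total_duration, mean_fly_bout, mean_rest_bout,
                                seed = seeds[[1]], first = first)
  accel <- synth_acceleration(schedule, flap_freq, flap_amp, noise_sd,
                              seed = seeds[[2]], injections = injections)
  gps <- synth_gps(schedule, colony, fly_speed, fix_dropout_p,
                   seed = seeds[[3]], injections = injections)
  mask <- if (include_mask)
    synth_mask_ratio(schedule, base_mpr, jitter_sd, injections,
                     seed = seeds[[4]])
  structure(list(accel = accel, gps = gps, mask = mask, schedule = schedule,
                 bird_id = bird_id, body_mass = body_mass, colony = colony),
            class = "sensor_bundle")
}

#' @export
print.sensor_bundle <- function(x, ...) {
  cat("<sensor_bundle>", x$bird_id, "\n",
      " duration:", attr(x$schedule, "total_duration"), "s in",
      nrow(x$schedule), "bouts\n",
      " accel:", nrow(x$accel), "samples @25Hz; gps:", nrow(x$gps),
      "@1Hz; mask:", if (is.null(x$mask)) "none" else
        paste(nrow(x$mask), "@30FPS"), "\n")
  invisible(x)
}
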