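#' Great-circle distance (haversine) in kilometres
#'
#' Spherical-Earth haversine distance with radius 6371.0 km.
#'
#' @param p1,p2 Each either `c(lat, lon)` in degrees or a two-column
#'   matrix/data frame of such points (recycled row-wise).
#' @return Numeric vector of distances in km.
#' @export
#' @examples
#' haversine_km(c(0, 0), c(1, 0))  # 111.195
haversine_km <- function(p1, p2) {
  as_mat <- function(p) {
    if (is.null(dim(p))) matrix(p, ncol = 2, byrow = TRUE) else as.matrix(p)
  }
  a <- as_mat(p1); b <- as_mat(p2)
  lat1 <- a[, 1] * pi / 180; lon1 <- a[, 2] * pi / 180
  lat2 <- b[, 1] * pi / 180; lon2 <- b[, 2] * pi / 180
  if (any(abs(c(a[, 1], b[, 1])) > 90) || any(abs(c(a[, 2], b[, 2])) > 180))
    stop("coordinates out of range")
  h <- sin((lat2 - lat1) / 2)^2 +
    cos(lat1) * cos(lat2) * sin((lon2 - lon1) / 2)^2
  2 * 6371.0 * asin(pmin(1, sqrt(h)))
}

#' Playback-controller configuration
#'
#' All timing constants default to the published firmware behaviour: 5 s of
#' consecutive flying to raise the GPS rate, a >= 3 min high-rate GPS hold,
#' standby only when the 10 most recent high-rate fixes are all 3D and more
#' than 1 km from the colony centre, ~60 s of video before and after
#' playback, and a 10 min refractory lockout after each session.
#'
#' @param colony `c(lat, lon)` of the colony centre.
#' @param consec_fly_s Consecutive flying seconds required to trigger
#'   transitions (default 5 s).
#' @param high_gps_hold_s Minimum high-rate GPS hold (default 180 s).
#' @param standby_fix_count Ring size of recent GPS fixes checked for
#'   standby eligibility (default 10).
#' @param exclusion_radius_km Geofence radius around the colony (default 1).
#' @param pre_record_s Video seconds before playback (default 60).
#' @param post_record_s Video seconds after playback (default 60).
#' @param refractory_s Lockout after a session ends (default 600 s).
#' @param cancel_nonfly_s Consecutive non-flying seconds that cancel a
#'   session during pre-record (default 5 s, mirroring the detection
#'   constant).
#' @param audio_set Audio stimulus labels drawn uniformly at playback.
#' @param low_gps_period_s GPS sampling period outside high-rate modes
#'   (default 60 s).
#' @param playback_len_s Symbolic playback duration in ticks (default 1).
#' @return A `controller_config` list.
#' @export
controller_config <- function(colony = c(40.539, 141.558),
                              consec_fly_s = 5, high_gps_hold_s = 180,
                              standby_fix_count = 10,
                              exclusion_radius_km = 1.0,
                              pre_record_s = 60, post_record_s = 60,
                              refractory_s = 600, cancel_nonfly_s = 5,
                              audio_set = c("predator", "noise"),
                              low_gps_period_s = 60, playback_len_s = 1) {
  cfg <- list(colony = colony, consec_fly_s = consec_fly_s,
              high_gps_hold_s = high_gps_hold_s,
              standby_fix_count = standby_fix_count,
              exclusion_radius_km = exclusion_radius_km,
              pre_record_s = pre_record_s, post_record_s = post_record_s,
              refractory_s = refractory_s, cancel_nonfly_s = cancel_nonfly_s,
              audio_set = audio_set, low_gps_period_s = low_gps_period_s,
              playback_len_s = playback_len_s)
  durs <- cfg[c("consec_fly_s", "high_gps_hold_s", "pre_record_s",
                "post_record_s", "refractory_s", "cancel_nonfly_s",
                "low_gps_period_s", "exclusion_radius_km")]
  if (any(unlist(durs) <= 0)) stop("all durations and the radius must be > 0")
  if (standby_fix_count < 1) stop("`standby_fix_count` must be >= 1")
  structure(cfg, class = "controller_config")
}

#' Standby eligibility of a recent-GPS ring
#'
#' TRUE iff the ring holds exactly `standby_fix_count` samples, every one
#' has a 3D fix, and every one lies strictly farther than the exclusion
#' radius from the colony centre. An under-full ring is ineligible (not an
#' error).
#'
#' @param ring Data frame with columns `lat`, `lon`, `fix3d` (most recent
#'   `standby_fix_count` consumed GPS samples).
#' @param config A [controller_config()].
#' @return Logical scalar.
#' @export
standby_eligible <- function(ring, config) {
  if (is.null(ring) || nrow(ring) < config$standby_fix_count) return(FALSE)
  ring <- ring[seq(nrow(ring) - config$standby_fix_count + 1, nrow(ring)), ]
  all(ring$fix3d) &&
    all(haversine_km(cbind(ring$lat, ring$lon), config$colony) >
          config$exclusion_radius_km)
}

#' Draw playback audio labels
#'
#' Uniform draw from the configured audio set; the controller uses this at
#' each `PLAYBACK_START`.
#'
#' @param n Number of draws.
#' @param config A [controller_config()].
#' @param seed Optional seed.
#' @return Character vector of audio labels.
#' @export
draw_audio <- function(n, config = controller_config(), seed = NULL) {
  with_seed(seed, sample(config$audio_set, n, replace = TRUE))
}

# Fresh controller state. Modes: LOW_GPS, HIGH_GPS, STANDBY, PRE_RECORD,
# PLAYBACK_POST, REFRACTORY.
controller_init <- function(config) {
  list(mode = "LOW_GPS", consec_fly = 0L, consec_nonfly = 0L,
       mode_entry = 0, high_entry = 0, video_start = NA_real_,
       playback_t = NA_real_, refr_start = NA_real_,
       ring = data.frame(lat = numeric(0), lon = numeric(0),
                         fix3d = logical(0)),
       last_t = NA_real_, session_open = FALSE, audio = NA_character_)
}

# One 1-s tick of the controller. `label` is the per-second behaviour
# estimate; `gps` a one-row data frame (lat, lon, speed, fix3d) or NULL when
# no sample is consumed this tick. Returns list(state, events, session)
# where `session` is non-NULL when a session closed this tick.
controller_step <- function(state, label, gps, t, config) {
  if (!is.na(state$last_t) && t <= state$last_t)
    stop("out-of-order tick timestamp at t = ", t)
  state$last_t <- t
  events <- list()
  session <- NULL
  emit <- function(kind, payload = NA_character_)
    events[[length(events) + 1L]] <<- list(t = t, kind = kind,
                                           payload = payload)

  flying <- identical(label, "flying")
  state$consec_fly <- if (flying) state$consec_fly + 1L else 0L
  state$consec_nonfly <- if (!flying) state$consec_nonfly + 1L else 0L

  # Ring of recent fixes: fed only by high-rate samples (HIGH_GPS/STANDBY).
  if (!is.null(gps) && state$mode %in% c("HIGH_GPS", "STANDBY")) {
    state$ring <- rbind(state$ring,
                        data.frame(lat = gps$lat, lon = gps$lon,
                                   fix3d = gps$fix3d))
    keep <- config$standby_fix_count
    if (nrow(state$ring) > keep)
      state$ring <- state$ring[seq(nrow(state$ring) - keep + 1,
                                   nrow(state$ring)), , drop = FALSE]
  }

  close_session <- function(cancelled) {
    session <<- data.frame(video_start = state$video_start,
                           playback_t = state$playback_t,
                           audio = state$audio, cancelled = cancelled,
                           end_t = t, stringsAsFactors = FALSE)
    state$video_start <<- NA_real_
    state$playback_t <<- NA_real_
    state$audio <<- NA_character_
    state$session_open <<- FALSE
    state$refr_start <<- t
    state$mode <<- "REFRACTORY"
    emit("GPS_MODE_LOW")
  }

  switch(state$mode,
    LOW_GPS = {
      if (state$consec_fly >= config$consec_fly_s) {
        state$mode <- "HIGH_GPS"
        state$high_entry <- t
        state$ring <- state$ring[0, ]
        emit("GPS_MODE_HIGH")
      }
    },
    HIGH_GPS = {
      if (state$consec_fly >= config$consec_fly_s) state$high_entry <- t
      if (standby_eligible(state$ring, config)) {
        state$mode <- "STANDBY"
        state$mode_entry <- t
        emit("STANDBY_ENTER")
      } else if (t - state$high_entry >= config$high_gps_hold_s) {
        state$mode <- "LOW_GPS"
        emit("GPS_MODE_LOW")
      }
    },
    STANDBY = {
      if (!standby_eligible(state$ring, config)) {
        state$mode <- "HIGH_GPS"
        state$high_entry <- t
      } else if (t - state$mode_entry >= config$consec_fly_s &&
                 state$consec_fly >= config$consec_fly_s) {
        state$mode <- "PRE_RECORD"
        state$video_start <- t
        state$session_open <- TRUE
        emit("VIDEO_START")
      }
    },
    PRE_RECORD = {
      if (state$consec_nonfly >= config$cancel_nonfly_s) {
        emit("SESSION_CANCELLED")
        emit("VIDEO_STOP")
        close_session(TRUE)
      } else if (t - state$video_start >= config$pre_record_s && flying) {
        state$audio <- sample(config$audio_set, 1L)
        state$playback_t <- t
        state$mode <- "PLAYBACK_POST"
        emit("PLAYBACK_START", state$audio)
      }
    },
    PLAYBACK_POST = {
      if (t == state$playback_t + config$playback_len_s)
        emit("PLAYBACK_END", state$audio)
      if (t - state$playback_t >= config$post_record_s) {
        emit("VIDEO_STOP")
        close_session(FALSE)
      }
    },
    REFRACTORY = {
      if (t - state$refr_start >= config$refractory_s) {
        state$mode <- "LOW_GPS"
        emit("REFRACTORY_END")
      }
    }
  )
  list(state = state, events = events, session = session)
}

#' Run the autonomous playback controller over a sensor bundle
#'
#' Drives the tick-synchronous (1 s) controller over the bundle's streams:
#' per-second behaviour labels come from `model` applied to the acceleration
#' stream (or from ground truth when `model` is `NULL`); GPS is consumed at
#' 1 Hz in high-rate modes (`HIGH_GPS`/`STANDBY`) and every
#' `low_gps_period_s` otherwise. The eligibility ring holds the most recent
#' high-rate fixes, so every `PLAYBACK_START` is backed by a fully 3D-fixed,
#' outside-geofence ring. Deterministic given `seed` (which drives the
#' audio draws).
#'
#' @param bundle A [synth_bundle()] result (mask stream not required).
#' @param model A [train_tree()] classifier, or `NULL` to use ground truth.
#' @param config A [controller_config()]; defaults to the bundle's colony.
#' @param seed Integer seed for the audio draws.
#' @return List with `events` (data frame `t, kind, payload`), `sessions`
#'   (data frame `session, video_start, playback_t, audio, cancelled,
#'   end_t, ring_min_km, ring_all_fix3d`) and `labels` (the per-second
#'   labels used).
#' @export
run_controller <- function(bundle, model = NULL,
                           config = controller_config(colony = bundle$colony),
                           seed = NULL) {
  fw <- accel_features(bundle$accel)
  n_tick <- length(fw$t_start)
  labels <- if (is.null(model)) {
    schedule_second_labels(bundle$schedule)[seq_len(n_tick)]
  } else {
    predict(model, fw$features)
  }
  gps <- bundle$gps
  gps_idx <- match(floor(fw$t_start), gps$t)

  with_seed(seed, {
    state <- controller_init(config)
    events <- vector("list", 0L)
    sessions <- list()
    ring_snaps <- list()
    for (k in seq_len(n_tick)) {
      t <- fw$t_start[k]
      high <- state$mode %in% c("HIGH_GPS", "STANDBY")
      take_gps <- !is.na(gps_idx[k]) &&
        (high || (t %% config$low_gps_period_s) == 0)
      g <- if (take_gps) gps[gps_idx[k], ] else NULL
      res <- controller_step(state, labels[k], g, t, config)
      state <- res$state
      if (length(res$events)) {
        events <- c(events, res$events)
        for (ev in res$events) if (ev$kind == "PLAYBACK_START") {
          ring <- state$ring
          ring_snaps[[length(ring_snaps) + 1L]] <- data.frame(
            ring_min_km = min(haversine_km(cbind(ring$lat, ring$lon),
                                           config$colony)),
            ring_all_fix3d = all(ring$fix3d))
        }
      }
      if (!is.null(res$session))
        sessions[[length(sessions) + 1L]] <- res$session
    }
    events_df <- if (length(events)) {
      data.frame(t = vapply(events, `[[`, numeric(1), "t"),
                 kind = vapply(events, `[[`, character(1), "kind"),
                 payload = vapply(events, `[[`, character(1), "payload"),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(t = numeric(0), kind = character(0),
                 payload = character(0))
    }
    sessions_df <- if (length(sessions)) {
      s <- do.call(rbind, sessions)
      s <- cbind(session = seq_len(nrow(s)) - 1L, s)
      snaps <- do.call(rbind, c(ring_snaps,
        list(data.frame(ring_min_km = numeric(0),
                        ring_all_fix3d = logical(0)))))
      s$ring_min_km <- NA_real_
      s$ring_all_fix3d <- NA
      played <- which(!is.na(s$playback_t))
      if (length(played)) {
        s$ring_min_km[played] <- snaps$ring_min_km
        s$ring_all_fix3d[played] <- snaps$ring_all_fix3d
      }
      s
    } else {
      data.frame(session = integer(0), video_start = numeric(0),
                 playback_t = numeric(0), audio = character(0),
                 cancelled = logical(0), end_t = numeric(0),
                 ring_min_km = numeric(0), ring_all_fix3d = logical(0))
    }
    list(events = events_df, sessions = sessions_df, labels = labels)
  })
}
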