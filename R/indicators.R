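#' Vectorial dynamic body acceleration (VeDBA)
#'
#' Per-sample VeDBA from 25 Hz tri-axial acceleration: the static component
#' of each axis is a centred running mean over `static_window_s`; the
#' dynamic component is sample minus static; VeDBA is the Euclidean norm of
#' the three dynamic components. Edge windows are truncated.
#'
#' @param accel Data frame `t, ax, ay, az` at 25 Hz.
#' @param static_window_s Static-estimation window in seconds (default 2 s).
#' @param fs Sampling rate (25 Hz).
#' @return Data frame `t, value` (VeDBA in g, one row per input sample).
#' @export
vedba <- function(accel, static_window_s = 2, fs = 25) {
  if (static_window_s <= 0) stop("`static_window_s` must be > 0")
  w <- round(static_window_s * fs)
  if (nrow(accel) < w)
    stop("series shorter than the static window (", w, " samples)")
  dx <- accel$ax - running_mean(accel$ax, w)
  dy <- accel$ay - running_mean(accel$ay, w)
  dz <- accel$az - running_mean(accel$az, w)
  data.frame(t = accel$t, value = sqrt(dx^2 + dy^2 + dz^2))
}

#' Smoothed VeDBA (S-VeDBA)
#'
#' Centred moving average of a VeDBA series over `window_s` seconds
#' (50 samples at 25 Hz), truncated at the edges.
#'
#' @param v Data frame `t, value` from [vedba()].
#' @param window_s Smoothing window in seconds (default 2 s).
#' @param fs Sampling rate of the series (25 Hz).
#' @return Data frame `t, value`.
#' @export
smooth_vedba <- function(v, window_s = 2, fs = 25) {
  if (window_s <= 0) stop("`window_s` must be > 0")
  data.frame(t = v$t, value = running_mean(v$value, round(window_s * fs)))
}

#' Absolute successive difference of ground speeds (AD-Speed)
#'
#' `|v_t - v_{t-1}|` between successive 1 Hz samples, timestamped at the
#' later sample so post-onset windows start exactly at onset.
#'
#' @param gps Data frame with `t` and `speed` (m/s) at 1 Hz, or a bare
#'   numeric speed vector.
#' @return Data frame `t, value` of length `n - 1`.
#' @export
ad_speed <- function(gps) {
  if (is.numeric(gps)) gps <- data.frame(t = seq_along(gps) - 1, speed = gps)
  if (nrow(gps) < 2L) stop("need at least 2 speed samples")
  data.frame(t = gps$t[-1L], value = abs(diff(gps$speed)))
}

#' Absolute successive difference of masked pixel ratios (AD-MPR)
#'
#' `|mpr_t - mpr_{t-1}|` between successive 30 FPS frames, timestamped at
#' the later frame.
#'
#' @param mask Data frame with `t` and `mpr` in `[0, 1]`, or a bare numeric
#'   mpr vector.
#' @return Data frame `t, value` of length `n - 1`.
#' @export
ad_mpr <- function(mask) {
  if (is.numeric(mask))
    mask <- data.frame(t = (seq_along(mask) - 1) / 30, mpr = mask)
  if (nrow(mask) < 2L) stop("need at least 2 frames")
  if (any(mask$mpr < 0 | mask$mpr > 1)) stop("mpr values must be in [0, 1]")
  data.frame(t = mask$t[-1L], value = abs(diff(mask$mpr)))
}

#' Align an indicator series to playback onset
#'
#' Shifts timestamps so the playback onset is time 0; pre-period samples
#' get negative times, during/post samples non-negative times.
#'
#' @param series Data frame `t, value`.
#' @param onset Playback onset in the series' time base; must lie inside
#'   the series range.
#' @param channel Optional channel tag (`"S_VEDBA"`, `"AD_SPEED"`,
#'   `"AD_MPR"`) recorded as an attribute.
#' @return An `indicator_series` data frame `t_rel, value`.
#' @export
align_to_onset <- function(series, onset, channel = NULL) {
  if (onset < min(series$t) || onset > max(series$t))
    stop("`onset` outside the series time range")
  out <- data.frame(t_rel = series$t - onset, value = series$value)
  attr(out, "channel") <- channel
  class(out) <- c("indicator_series", "data.frame")
  out
}

#' All three response indicators for one playback session
#'
#' Computes S-VeDBA (from 25 Hz acceleration), AD-Speed (from 1 Hz GPS
#' ground speed) and AD-MPR (from the 30 FPS mask-ratio stream), each
#' aligned to the playback onset.
#'
#' @param bundle A [synth_bundle()] result (needs the mask stream for
#'   AD-MPR).
#' @param onset Playback onset in seconds since stream start.
#' @param static_window_s,smooth_window_s VeDBA parameters.
#' @return Named list of `indicator_series` (`S_VEDBA`, `AD_SPEED`,
#'   `AD_MPR`; the latter `NULL` without a mask stream).
#' @export
session_indicators <- function(bundle, onset, static_window_s = 2,
                               smooth_window_s = 2) {
  sv <- smooth_vedba(vedba(bundle$accel, static_window_s), smooth_window_s)
  out <- list(
    S_VEDBA = align_to_onset(sv, onset, "S_VEDBA"),
    AD_SPEED = align_to_onset(ad_speed(bundle$gps), onset, "AD_SPEED"),
    AD_MPR = if (!is.null(bundle$mask))
      align_to_onset(ad_mpr(bundle$mask), onset, "AD_MPR"))
  out
}
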