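#' Track configuration
#'
#' Geometry and calibration of the 1D track: physical length, the scale
#' converting rotary-encoder ticks to millimetres, and whether the track
#' is circular (a belt or looped virtual corridor) so that positions wrap
#' at `track_length_mm`.
#'
#' @param track_length_mm Track length in mm (> 0).
#' @param scale_mm_per_tick Linear distance per encoder tick in mm (> 0).
#' @param circular Does position wrap at the track length?
#' @return A `track_config` record.
#' @export
track_config <- function(track_length_mm, scale_mm_per_tick, circular = TRUE) {
  stopifnot(
    is_scalar_number(track_length_mm), track_length_mm > 0,
    is_scalar_number(scale_mm_per_tick), scale_mm_per_tick > 0
  )
  structure(
    list(
      track_length_mm = as.double(track_length_mm),
      scale_mm_per_tick = as.double(scale_mm_per_tick),
      circular = isTRUE(circular)
    ),
    class = "track_config"
  )
}

#' Integrated position state
#'
#' Position along the track in mm (always in `[0, track_length_mm)`),
#' the lap counter, and raw cumulative tick count.  `mm_since_wrap`
#' tracks distance travelled since the last lap increment and backs the
#' guard window that prevents a lap-reset sensor event from double
#' counting a lap the wrap logic already counted.
#'
#' @param position_mm Starting position in mm.
#' @param lap Starting lap count.
#' @param last_update_ms Time of last update.
#' @return A `track_state` record.
#' @export
track_state <- function(position_mm = 0, lap = 0L, last_update_ms = 0L) {
  structure(
    list(
      position_mm = as.double(position_mm),
      lap = as.integer(lap),
      cumulative_ticks = 0,
      last_update_ms = as.double(last_update_ms),
      mm_since_wrap = as.double(position_mm)
    ),
    class = "track_state"
  )
}

#' Integrate encoder ticks into position
#'
#' Advances position by `delta_ticks * scale`.  Crossing the track length
#' advances the lap count and wraps position by subtraction, preserving
#' the residual distance.  Backward motion floors at 0 within a lap (laps
#' never decrement).
#'
#' @param s A [track_state()].
#' @param cfg A [track_config()].
#' @param delta_ticks Signed tick count since the last update.
#' @param now_ms Current time (>= `s$last_update_ms`).
#' @return Updated `track_state`.
#' @export
integrate_ticks <- function(s, cfg, delta_ticks, now_ms) {
  stopifnot(now_ms >= s$last_update_ms)
  L <- cfg$track_length_mm
  delta_mm <- delta_ticks * cfg$scale_mm_per_tick
  pos <- s$position_mm + delta_mm
  lap <- s$lap
  travelled <- s$mm_since_wrap + delta_mm
  if (pos < 0) {
    pos <- 0
    travelled <- max(travelled, 0)
  }
  if (cfg$circular) {
    while (pos >= L) {
      pos <- pos - L
      lap <- lap + 1L
      travelled <- pos # distance since the wrap just counted
    }
  }
  s$position_mm <- pos
  s$lap <- lap
  s$cumulative_ticks <- s$cumulative_ticks + delta_ticks
  s$last_update_ms <- as.double(now_ms)
  s$mm_since_wrap <- travelled
  s
}

#' Apply a lap-reset sensor event
#'
#' A physical sensor marks each complete belt revolution.  Because tick
#' integration and the physical belt can drift apart (belt slip), the
#' reset re-anchors position to 0 and reports the signed drift along the
#' shorter arc.  The lap counter increments only if the wrap logic has
#' not already counted this revolution: resets arriving within a guard
#' window of `L/4` of travel after a wrap do not increment again.
#'
#' @param s A [track_state()].
#' @param cfg A [track_config()].
#' @param guard_frac Guard window as a fraction of track length.
#' @return `list(state =, drift_mm =)` — state with position 0, and the
#'   signed drift in mm at the moment of reset.
#' @export
apply_lap_reset <- function(s, cfg, guard_frac = 0.25) {
  L <- cfg$track_length_mm
  drift <- circular_signed(s$position_mm, 0, L)
  in_guard <- s$mm_since_wrap < guard_frac * L
  if (!in_guard) s$lap <- s$lap + 1L
  s$position_mm <- 0
  s$mm_since_wrap <- 0
  list(state = s, drift_mm = drift)
}

#' Calibrate the tick-to-distance scale
#'
#' With a lap-reset sensor installed, running the belt for a few complete
#' revolutions gives tick counts per known belt length; the scale is the
#' belt length divided by the mean count.
#'
#' @param tick_counts_per_lap Integer vector, one complete lap each.
#' @param belt_length_mm Physical belt length in mm.
#' @return Scale in mm per tick.
#' @examples
#' calibrate_scale(c(4000, 4000, 4000), 2000) # 0.5
#' @export
calibrate_scale <- function(tick_counts_per_lap, belt_length_mm) {
  if (length(tick_counts_per_lap) < 1L || mean(tick_counts_per_lap) == 0) {
    abort("need at least one complete lap with a nonzero tick count.",
          class = "trackloop_calibration_error")
  }
  belt_length_mm / mean(tick_counts_per_lap)
}

#' Per-lap tracking error against ground truth
#'
#' Compares a logged position stream with a ground-truth stream (from the
#' virtual rig, or any external benchmark) lap by lap: the lap-time error
#' is the difference between logged and true lap-completion times; the
#' position error is the circular distance of the logged position from 0
#' at the true completion instant.
#'
#' @param logged,truth Data frames with columns `t_ms`, `position_mm`,
#'   `lap`.
#' @param track_length_mm Track length for circular distance.
#' @return A tibble with one row per common lap: `lap`,
#'   `lap_time_error_s`, `lap_position_error_mm`.  If the streams do not
#'   cover the same laps the report is truncated to the common laps and
#'   carries a `truncated` attribute.
#' @export
tracking_error_report <- function(logged, truth, track_length_mm) {
  completion_times <- function(df, laps) {
    vapply(laps, function(k) min(df$t_ms[df$lap >= k]), numeric(1))
  }
  max_common <- min(max(logged$lap), max(truth$lap))
  truncated <- max(logged$lap) != max(truth$lap)
  if (truncated) {
    warn(sprintf("lap-count mismatch (logged %d, truth %d); truncating to %d laps",
                 max(logged$lap), max(truth$lap), max_common))
  }
  laps <- seq_len(max_common)
  if (max_common < 1L) {
    return(tibble(lap = integer(), lap_time_error_s = numeric(),
                  lap_position_error_mm = numeric()))
  }
  t_logged <- completion_times(logged, laps)
  t_truth <- completion_times(truth, laps)
  pos_err <- vapply(t_truth, function(tt) {
    i <- findInterval(tt, logged$t_ms)
    p <- if (i >= 1L) logged$position_mm[i] else logged$position_mm[1]
    circular_distance(p, 0, track_length_mm)
  }, numeric(1))
  out <- tibble(
    lap = laps,
    lap_time_error_s = (t_logged - t_truth) / 1000,
    lap_position_error_mm = pos_err
  )
  attr(out, "truncated") <- truncated
  out
}
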