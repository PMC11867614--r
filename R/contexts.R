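#' Reward / stimulus zone
#'
#' A zone is a location plus a radius: the interval of track positions
#' within `radius_mm` of `center_mm`, wrapping circularly on circular
#' tracks.  Zones give user-specified tolerance for where an animal can
#' trigger location-bound stimuli (rewards, cues).
#'
#' @param center_mm Zone centre in mm.
#' @param radius_mm Zone radius in mm (> 0).
#' @export
zone <- function(center_mm, radius_mm) {
  stopifnot(is_scalar_number(center_mm), is_scalar_number(radius_mm),
            radius_mm > 0)
  structure(list(center_mm = as.double(center_mm),
                 radius_mm = as.double(radius_mm)),
            class = "track_zone")
}

# Index of the first zone containing `position_mm`, or 0L.
zone_hit <- function(position_mm, zones, cfg) {
  if (length(zones) == 0L) return(0L)
  for (i in seq_along(zones)) {
    z <- zones[[i]]
    d <- if (cfg$circular) {
      circular_distance(position_mm, z$center_mm, cfg$track_length_mm)
    } else {
      abs(position_mm - z$center_mm)
    }
    if (d <= z$radius_mm) return(i)
  }
  0L
}

#' Context activation decorators
#'
#' A decorator wraps a context's activation rule with an extra condition
#' (a conjunction), making behavioral paradigms composable without new
#' code.  Supported kinds:
#'
#' * `lap_parity`: active only on `"even"` or `"odd"` laps.
#' * `time_window`: active only for `start_ms <= t < end_ms`.
#' * `lap_range`: active only for `min <= lap <= max`.
#' * `alternation`: active on alternating blocks of `period_laps` laps,
#'   starting with block parity `phase` (0 or 1).
#'
#' @param kind One of `"lap_parity"`, `"time_window"`, `"lap_range"`,
#'   `"alternation"`.
#' @param ... Parameters for the kind: `parity`; `start_ms`, `end_ms`;
#'   `min`, `max`; `period_laps`, `phase`.
#' @return A `decorator_spec`.
#' @examples
#' decorator("lap_parity", parity = "even")
#' decorator("time_window", start_ms = 3e5) # only after 5 min
#' @export
decorator <- function(kind, ...) {
  params <- list(...)
  kinds <- c("lap_parity", "time_window", "lap_range", "alternation")
  if (length(kind) != 1L || !kind %in% kinds) {
    abort(paste0("unknown decorator kind '", paste(kind, collapse = ","),
                 "'; must be one of ", paste(kinds, collapse = ", ")),
          class = "trackloop_settings_error")
  }
  spec <- switch(kind,
    lap_parity = {
      parity <- match.arg(params$parity %||% "even", c("even", "odd"))
      list(parity = parity)
    },
    time_window = {
      start_ms <- params$start_ms %||% 0
      end_ms <- params$end_ms %||% Inf
      if (end_ms <= start_ms) abort("time_window end must exceed start.",
                                    class = "trackloop_settings_error")
      list(start_ms = start_ms, end_ms = end_ms)
    },
    lap_range = {
      lo <- params$min %||% 0
      hi <- params$max %||% Inf
      if (hi < lo) abort("lap_range max must be >= min.",
                         class = "trackloop_settings_error")
      list(min = lo, max = hi)
    },
    alternation = {
      period <- params$period_laps %||% 1
      if (period < 1) abort("alternation period must be >= 1 lap.",
                            class = "trackloop_settings_error")
      list(period_laps = period, phase = (params$phase %||% 0) %% 2)
    }
  )
  structure(c(list(kind = kind), spec), class = "decorator_spec")
}

# Does the decorator's own condition hold in this experiment state?
decorator_active <- function(spec, state) {
  switch(spec$kind,
    lap_parity = (state$track$lap %% 2 == if (spec$parity == "even") 0 else 1),
    time_window = (state$t_ms >= spec$start_ms && state$t_ms < spec$end_ms),
    lap_range = (state$track$lap >= spec$min && state$track$lap <= spec$max),
    alternation = ((state$track$lap %/% spec$period_laps) %% 2 == spec$phase)
  )
}

#' Base activation rule of a context
#'
#' The undecorated check: a context with no zones is global (always
#' active while the experiment runs); otherwise it is active when the
#' animal's position lies within any of its zones (circular distance on
#' circular tracks).
#'
#' @param context A context definition (see [context_list()]).
#' @param state Experiment state with fields `t_ms` and `track`.
#' @param cfg A [track_config()].
#' @return Logical.
#' @export
base_check <- function(context, state, cfg) {
  if (length(context$zones) == 0L) return(TRUE)
  zone_hit(state$track$position_mm, context$zones, cfg) > 0L
}

#' Wrap an activation rule with a decorator
#'
#' Returns a new predicate equal to the decorator's condition AND the
#' inner predicate.  All decorators are conjunctions, so stacking order
#' changes nothing about the resulting activation trace.
#'
#' @param check_fn Predicate `f(context, state, cfg)`.
#' @param spec A [decorator()].
#' @return A new predicate with the same signature.
#' @export
decorate <- function(check_fn, spec) {
  force(check_fn); force(spec)
  function(context, state, cfg) {
    decorator_active(spec, state) && check_fn(context, state, cfg)
  }
}

#' Define a context list
#'
#' A context list groups stimuli that activate concurrently under a
#' common rule: a set of zones (empty = global), an ordered stack of
#' decorators, and the device actions to send on activation edges.
#' Reward contexts additionally carry a reward `mode`: `"non_operant"`
#' rewards on zone entry, `"operant"` only when the animal licks inside
#' the zone — in both cases at most once per lap per zone.
#'
#' @param id Unique context id string.
#' @param zones List of [zone()]s; empty for a global context.
#' @param decorators List of [decorator()]s, applied as conjunctions.
#' @param targets List of device targets, each a list with `route`
#'   (character vector), `start_action`, `stop_action`, and optional
#'   `payload` (sent with both).
#' @param mode `"none"`, `"operant"`, or `"non_operant"`.
#' @param reward_duration_ms Valve-open duration sent on reward triggers.
#' @return A `context_list` definition.
#' @export
context_list <- function(id, zones = list(), decorators = list(),
                         targets = list(), mode = c("none", "operant", "non_operant"),
                         reward_duration_ms = 50) {
  mode <- match.arg(mode)
  structure(
    list(
      id = as.character(id), zones = zones, decorators = decorators,
      targets = targets, mode = mode,
      reward_duration_ms = as.double(reward_duration_ms),
      active = FALSE,
      rewarded_lap = rep(-1L, max(1L, length(zones)))
    ),
    class = "context_list"
  )
}

# Full (decorated) activation check, decorators composed outermost-last.
context_active <- function(context, state, cfg) {
  fn <- base_check
  for (spec in context$decorators) fn <- decorate(fn, spec)
  fn(context, state, cfg)
}

#' Evaluate the reward rule of a context
#'
#' Given the current state, decides whether a reward context should
#' trigger its valve now: `"trigger"` (deliver and latch for this lap),
#' `"hold"` (operant mode, in zone but no lick yet), or `"none"`.
#'
#' @param context A reward [context_list()] with its runtime latch.
#' @param state Experiment state (`track`, `licking`).
#' @param cfg A [track_config()].
#' @return `list(status = "trigger"|"hold"|"none", zone = index)`.
#' @export
evaluate_reward <- function(context, state, cfg) {
  if (context$mode == "none") return(list(status = "none", zone = 0L))
  zi <- zone_hit(state$track$position_mm, context$zones, cfg)
  if (zi == 0L) return(list(status = "none", zone = 0L))
  if (context$rewarded_lap[zi] == state$track$lap) {
    return(list(status = "none", zone = zi))
  }
  if (context$mode == "non_operant" || isTRUE(state$licking)) {
    list(status = "trigger", zone = zi)
  } else {
    list(status = "hold", zone = zi)
  }
}
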