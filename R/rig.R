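#' Stochastic mouse behavior model
#'
#' Parameters of the simulated runner: mean running speed with
#' Ornstein-Uhlenbeck-like fluctuation, random pauses, and lick rates
#' that rise inside reward zones.  The defaults describe a motivated
#' adult mouse on a 2 m belt: ~20 cm/s average running speed, occasional
#' 1 s pauses, sparse spontaneous licking with a burst near reward sites.
#'
#' @param mean_speed_mm_s Mean running speed (mm/s).
#' @param speed_sd Stationary SD of the speed fluctuation (mm/s).
#' @param pause_prob_per_s Probability per second of starting a pause.
#' @param pause_duration_s Pause length in seconds.
#' @param lick_rate_base_hz Spontaneous lick rate (Hz).
#' @param lick_rate_zone_hz Lick rate inside a reward zone (Hz).
#' @return A `mouse_model` record.
#' @export
mouse_model <- function(mean_speed_mm_s = 200, speed_sd = 40,
                        pause_prob_per_s = 0.05, pause_duration_s = 1,
                        lick_rate_base_hz = 0.5, lick_rate_zone_hz = 8) {
  stopifnot(mean_speed_mm_s >= 0, speed_sd >= 0,
            pause_prob_per_s >= 0, pause_prob_per_s <= 1,
            pause_duration_s >= 0, lick_rate_base_hz >= 0,
            lick_rate_zone_hz >= 0)
  structure(
    list(mean_speed_mm_s = mean_speed_mm_s, speed_sd = speed_sd,
         pause_prob_per_s = pause_prob_per_s,
         pause_duration_s = pause_duration_s,
         lick_rate_base_hz = lick_rate_base_hz,
         lick_rate_zone_hz = lick_rate_zone_hz),
    class = "mouse_model"
  )
}

#' Simulate a mouse running on the track
#'
#' Generates ground-truth behavior on a 10 ms grid (the transmission
#' window of the position controller): speed follows a clipped
#' Ornstein-Uhlenbeck process with random pauses; encoder ticks are the
#' quantized displacement with the fractional remainder carried forward
#' (so total ticks x scale never drifts from true displacement by more
#' than one tick); licks are Bernoulli per window with a zone-elevated
#' rate.  Belt slip can be injected: the physical belt then completes a
#' revolution only every `track_length + belt_slip_mm_per_lap` of
#' wheel-measured distance, which is what the lap-reset sensor reports.
#'
#' All randomness flows from `seed` through independent named substreams
#' (motion, licks), so the two are separately reproducible.
#'
#' @param model A [mouse_model()].
#' @param cfg A [track_config()].
#' @param duration_ms Simulation length (ms).
#' @param zones Optional list of [zone()]s that elevate the lick rate.
#' @param seed Integer seed.
#' @param belt_slip_mm_per_lap Injected encoder-vs-belt slip per lap (mm).
#' @return A `mouse_sim` list: `ticks` (tibble `t_ms`, `ticks`), `licks`
#'   (tibble `t_ms`), `lap_resets` (tibble `t_ms`), `truth` (tibble
#'   `t_ms`, `position_mm`, `lap`, `speed_mm_s`, `cum_mm`), plus the
#'   inputs.
#' @export
simulate_mouse <- function(model, cfg, duration_ms, zones = NULL, seed = 1L,
                           belt_slip_mm_per_lap = 0) {
  stopifnot(cfg$scale_mm_per_tick > 0, duration_ms > 0)
  dt <- 0.01
  n <- floor(duration_ms / 10)
  t_ms <- seq_len(n) * 10

  # --- motion substream ------------------------------------------------
  set.seed(substream_seed(seed, 1L))
  eps <- rnorm(n)
  pause_draw <- runif(n)
  theta <- 1 # 1/s relaxation toward the mean speed
  v <- numeric(n)
  vi <- model$mean_speed_mm_s
  pause_until <- -1
  for (i in seq_len(n)) {
    ti <- i * dt
    if (ti >= pause_until && pause_draw[i] < model$pause_prob_per_s * dt) {
      pause_until <- ti + model$pause_duration_s
    }
    vi <- vi + theta * (model$mean_speed_mm_s - vi) * dt +
      model$speed_sd * sqrt(dt) * eps[i]
    vi <- max(vi, 0)
    v[i] <- if (ti < pause_until) 0 else vi
  }
  cum_mm <- cumsum(v * dt)

  # encoder ticks: quantized displacement, remainder carried
  total_ticks <- floor(cum_mm / cfg$scale_mm_per_tick)
  ticks <- diff(c(0, total_ticks))

  # physical belt: one revolution per belt_rev of measured distance
  belt_rev <- cfg$track_length_mm + belt_slip_mm_per_lap
  lap <- as.integer(cum_mm %/% belt_rev)
  position_mm <- (cum_mm %% belt_rev) * (cfg$track_length_mm / belt_rev)
  reset_idx <- which(diff(c(0L, lap)) > 0L)

  # --- lick substream --------------------------------------------------
  set.seed(substream_seed(seed, 2L))
  rate <- rep(model$lick_rate_base_hz, n)
  if (length(zones) > 0) {
    in_zone <- rep(FALSE, n)
    for (z in zones) {
      d <- if (cfg$circular) {
        circular_distance(position_mm, z$center_mm, cfg$track_length_mm)
      } else {
        abs(position_mm - z$center_mm)
      }
      in_zone <- in_zone | (d <= z$radius_mm)
    }
    rate[in_zone] <- model$lick_rate_zone_hz
  }
  lick <- runif(n) < pmin(rate * dt, 1)

  structure(
    list(
      ticks = tibble(t_ms = t_ms, ticks = as.double(ticks)),
      licks = tibble(t_ms = t_ms[lick]),
      lap_resets = tibble(t_ms = t_ms[reset_idx]),
      truth = tibble(t_ms = t_ms, position_mm = position_mm, lap = lap,
                     speed_mm_s = v, cum_mm = cum_mm),
      model = model, cfg = cfg, seed = seed, dt = dt,
      belt_slip_mm_per_lap = belt_slip_mm_per_lap
    ),
    class = "mouse_sim"
  )
}

#' Virtual position controller
#'
#' Converts a simulated tick stream into the event-driven message stream
#' a hardware position controller would emit: a `delta` message only for
#' 10 ms windows with nonzero tick counts (zero-velocity periods generate
#' no packets), plus a `lap_reset` message whenever the physical belt
#' completes a revolution.
#'
#' @param sim A [simulate_mouse()] result.
#' @return Chronologically ordered list of [message_packet()]s, each with
#'   `t_ms` set.
#' @export
virtual_position_controller <- function(sim) {
  msgs <- list()
  id <- 0L
  nz <- which(sim$ticks$ticks != 0)
  reset_t <- sim$lap_resets$t_ms
  events <- rbind(
    if (length(nz)) data.frame(t = sim$ticks$t_ms[nz], kind = "delta",
                               ticks = sim$ticks$ticks[nz]),
    if (length(reset_t)) data.frame(t = reset_t, kind = "reset", ticks = 0)
  )
  if (is.null(events) || nrow(events) == 0L) return(list())
  # at equal times the delta precedes the reset, as the counter is read first
  events <- events[order(events$t, ifelse(events$kind == "delta", 0, 1)), ]
  for (i in seq_len(nrow(events))) {
    id <- id + 1L
    e <- events[i, ]
    msgs[[i]] <- if (e$kind == "delta") {
      message_packet("position", "delta", list(ticks = e$ticks),
                     id = id, t_ms = e$t)
    } else {
      message_packet("position", "lap_reset", list(), id = id, t_ms = e$t)
    }
  }
  msgs
}

#' Virtual behavior controller
#'
#' A software stand-in for the GPIO board: receives valve/LED/tone and
#' sync commands, records each actuation with its receipt time and
#' duration, acknowledges every datagram exactly once per message id
#' (duplicates are deduplicated), and tolerates unknown actions by
#' acknowledging and dead-lettering them.  Devices actuate regardless of
#' whether an experiment is running, so pre-run test pulses work.
#'
#' @return A `virtual_behavior_controller` environment with `$log()`
#'   returning the actuation tibble and `$peer` for transports.
#' @export
virtual_behavior_controller <- function() {
  env <- new.env(parent = emptyenv())
  env$actuations <- list()
  env$dead_letters <- 0L
  env$now_ms <- 0
  handler <- function(m) {
    head <- m$route[[1]]
    t_recv <- m$t_ms %||% env$now_ms
    if (head %in% c("valve", "led", "tone", "gpio", "sync")) {
      env$actuations[[length(env$actuations) + 1L]] <- tibble(
        t_ms = as.double(t_recv), device = head,
        action = m$action %||% NA_character_,
        duration_ms = as.double(m$payload$duration_ms %||% NA),
        msg_id = as.double(m$id %||% NA)
      )
    } else {
      env$dead_letters <- env$dead_letters + 1L
    }
    NULL
  }
  env$peer <- ack_peer(handler)
  env$log <- function() {
    if (length(env$actuations) == 0L) {
      tibble(t_ms = double(), device = character(), action = character(),
             duration_ms = double(), msg_id = double())
    } else {
      dplyr::bind_rows(env$actuations)
    }
  }
  class(env) <- "virtual_behavior_controller"
  env
}

#' Virtual display stub
#'
#' Protocol-level stand-in for the VR renderer: records every position
#' and scene packet with send and receive times under a scripted
#' transport delay, so closed-loop latency and scene-switch schedules can
#' be measured without any rendering.
#'
#' @param delay_ms Scripted one-way transport delay.
#' @return A `virtual_display` environment with `$receive(m, send_t)` and
#'   `$log()`.
#' @export
virtual_display <- function(delay_ms = 0) {
  env <- new.env(parent = emptyenv())
  env$frames <- list()
  env$scene_id <- "default"
  env$delay_ms <- as.double(delay_ms)
  env$receive <- function(m, send_t) {
    recv_t <- send_t + env$delay_ms
    if (identical(m$action, "scene")) {
      env$scene_id <- as.character(m$payload$scene_id %||% env$scene_id)
    }
    env$frames[[length(env$frames) + 1L]] <- tibble(
      send_t_ms = as.double(send_t), recv_t_ms = as.double(recv_t),
      latency_ms = as.double(recv_t - send_t),
      position_mm = as.double(m$payload$position_mm %||% NA),
      scene_id = env$scene_id, action = m$action %||% NA_character_
    )
  }
  env$log <- function() {
    if (length(env$frames) == 0L) {
      tibble(send_t_ms = double(), recv_t_ms = double(), latency_ms = double(),
             position_mm = double(), scene_id = character(), action = character())
    } else {
      dplyr::bind_rows(env$frames)
    }
  }
  class(env) <- "virtual_display"
  env
}

#' Assemble a complete virtual rig
#'
#' Bundles the simulated mouse, the virtual position controller (as a
#' precomputed message schedule), the virtual behavior controller (with
#' its acknowledged transport), and the display stub into the object
#' [run_experiment()] drives.
#'
#' @param model A [mouse_model()].
#' @param cfg A [track_config()].
#' @param duration_ms Session length (ms).
#' @param zones Reward zones that elevate the simulated lick rate.
#' @param seed Integer seed for all rig randomness.
#' @param belt_slip_mm_per_lap Injected belt slip (mm/lap).
#' @param display_delay_ms Scripted display transport delay.
#' @param behavior_transport_factory Function `f(peer)` building the
#'   transport to the behavior controller (default lossless); use
#'   [transport_droplist()] variants to script loss.
#' @return A `virtual_rig` environment.
#' @export
virtual_rig <- function(model, cfg, duration_ms, zones = NULL, seed = 1L,
                        belt_slip_mm_per_lap = 0, display_delay_ms = 0,
                        behavior_transport_factory = transport_lossless) {
  sim <- simulate_mouse(model, cfg, duration_ms, zones = zones, seed = seed,
                        belt_slip_mm_per_lap = belt_slip_mm_per_lap)
  pos_msgs <- virtual_position_controller(sim)
  lick_msgs <- lapply(seq_len(nrow(sim$licks)), function(i) {
    message_packet("lick", "on", list(), id = i, t_ms = sim$licks$t_ms[i])
  })
  inbox <- c(pos_msgs, lick_msgs)
  times <- vapply(inbox, function(m) m$t_ms, numeric(1))
  ord <- order(times)
  inbox <- inbox[ord]
  times <- times[ord]

  env <- new.env(parent = emptyenv())
  env$sim <- sim
  env$inbox <- inbox
  env$inbox_t <- times
  env$behavior <- virtual_behavior_controller()
  env$behavior_transport <- behavior_transport_factory(env$behavior$peer)
  env$display <- virtual_display(display_delay_ms)
  class(env) <- "virtual_rig"
  env
}

#' Pull the rig messages for one event-loop window
#' @param rig A [virtual_rig()].
#' @param t0,t1 Window `(t0, t1]` in ms.
#' @return List of messages.
#' @export
rig_poll <- function(rig, t0, t1) {
  rig$inbox[rig$inbox_t > t0 & rig$inbox_t <= t1]
}

#' Deliver an engine message to the rig devices
#'
#' Routes on the message head: display packets go to the display stub;
#' everything else goes to the behavior controller over its acknowledged
#' transport.
#'
#' @param rig A [virtual_rig()].
#' @param m A [message_packet()].
#' @param now_ms Send time.
#' @return Invisibly, whether the message was acknowledged (behavior
#'   controller) or logged (display).
#' @export
rig_deliver <- function(rig, m, now_ms) {
  head <- m$route[[1]]
  if (head == "display") {
    rig$display$receive(m, now_ms)
    return(invisible(TRUE))
  }
  rig$behavior$now_ms <- now_ms
  reply <- transport_send(rig$behavior_transport, encode_message(m))
  invisible(!is.null(reply))
}
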