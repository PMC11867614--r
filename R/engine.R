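#' Initialize a task engine from settings
#'
#' The engine is the central event loop state: track integration,
#' experiment clock, context lists with their runtime latches, and a
#' monotone outgoing message id counter.
#'
#' @param settings A [validate_settings()] result (or raw list / JSON
#'   path, which will be validated).
#' @return A `task_engine` object.
#' @export
engine_init <- function(settings) {
  if (!inherits(settings, "settings_spec")) settings <- validate_settings(settings)
  structure(
    list(
      settings = settings,
      cfg = settings$track,
      track = track_state(),
      t_ms = 0,
      licking = FALSE,
      reward_count = 0L,
      running = FALSE,
      contexts = settings$contexts,
      msg_id = 0L,
      dead_letters = 0L
    ),
    class = "task_engine"
  )
}

engine_next_id <- function(engine) {
  engine$msg_id <- engine$msg_id + 1L
  list(engine = engine, id = engine$msg_id)
}

engine_state <- function(engine) {
  list(t_ms = engine$t_ms, track = engine$track, licking = engine$licking,
       reward_count = engine$reward_count, running = engine$running)
}

new_record <- function(t_ms, kind, ...) {
  c(list(t_ms = as.double(t_ms), kind = kind), list(...))
}

#' Advance the engine by one event-loop step
#'
#' Processes the inbound messages (position deltas, lap resets, licks,
#' acks), then evaluates every context list in settings order against the
#' updated state.  Start/stop action messages are emitted only on
#' activation edges; every emitted message and state change yields a
#' timestamped behavior record.  Malformed inbound messages become
#' dead-letter error records; the step always completes.
#'
#' @param engine A [engine_init()] engine.
#' @param now_ms Logical clock for this step (monotone).
#' @param inbox List of [message_packet()]s received since last step.
#' @return `list(engine =, outbox = list of messages, records = list)`.
#' @export
engine_step <- function(engine, now_ms, inbox = list()) {
  records <- list()
  outbox <- list()
  cfg <- engine$cfg
  engine$t_ms <- as.double(now_ms)

  for (m in inbox) {
    if (!inherits(m, "bm_message")) {
      engine$dead_letters <- engine$dead_letters + 1L
      records[[length(records) + 1L]] <-
        new_record(now_ms, "error", reason = "malformed inbound message")
      next
    }
    head <- m$route[[1]]
    if (head == "position" && identical(m$action, "delta")) {
      prev_lap <- engine$track$lap
      engine$track <- integrate_ticks(engine$track, cfg,
                                      m$payload$ticks, now_ms)
      records[[length(records) + 1L]] <-
        new_record(now_ms, "position", position_mm = engine$track$position_mm,
                   lap = engine$track$lap)
      if (engine$track$lap > prev_lap) {
        records[[length(records) + 1L]] <-
          new_record(now_ms, "lap", lap = engine$track$lap, source = "wrap")
      }
    } else if (head == "position" && identical(m$action, "lap_reset")) {
      prev_lap <- engine$track$lap
      res <- apply_lap_reset(engine$track, cfg)
      engine$track <- res$state
      records[[length(records) + 1L]] <-
        new_record(now_ms, "lap", lap = engine$track$lap, source = "reset",
                   drift_mm = res$drift_mm,
                   counted = engine$track$lap > prev_lap)
    } else if (head == "lick") {
      engine$licking <- TRUE
      records[[length(records) + 1L]] <- new_record(now_ms, "lick")
    } else if (head == "ack") {
      records[[length(records) + 1L]] <-
        new_record(now_ms, "message_in", route = "ack",
                   ack_id = m$payload$id %||% NA)
    } else {
      engine$dead_letters <- engine$dead_letters + 1L
      records[[length(records) + 1L]] <-
        new_record(now_ms, "error", reason = "unmatched route",
                   route = paste(m$route, collapse = "/"))
    }
  }

  if (engine$running) {
    state <- engine_state(engine)
    for (i in seq_along(engine$contexts)) {
      ctx <- engine$contexts[[i]]
      act <- context_active(ctx, state, cfg)
      if (act != ctx$active) {
        for (tg in ctx$targets) {
          nid <- engine_next_id(engine); engine <- nid$engine
          action <- if (act) tg$start_action else tg$stop_action
          msg <- message_packet(tg$route, action, tg$payload,
                                id = nid$id, t_ms = now_ms)
          outbox[[length(outbox) + 1L]] <- msg
          records[[length(records) + 1L]] <-
            new_record(now_ms, "message_out",
                       route = paste(tg$route, collapse = "/"),
                       action = action, msg_id = nid$id)
        }
        records[[length(records) + 1L]] <-
          new_record(now_ms, if (act) "context_start" else "context_stop",
                     context = ctx$id)
        ctx$active <- act
      }
      if (ctx$mode != "none" && ctx$active) {
        ev <- evaluate_reward(ctx, state, cfg)
        if (ev$status == "trigger") {
          ctx$rewarded_lap[ev$zone] <- state$track$lap
          engine$reward_count <- engine$reward_count + 1L
          nid <- engine_next_id(engine); engine <- nid$engine
          msg <- message_packet("valve", "open",
                                list(duration_ms = ctx$reward_duration_ms,
                                     context = ctx$id),
                                id = nid$id, t_ms = now_ms)
          outbox[[length(outbox) + 1L]] <- msg
          records[[length(records) + 1L]] <-
            new_record(now_ms, "reward", context = ctx$id, zone = ev$zone,
                       lap = state$track$lap, msg_id = nid$id)
        }
      }
      engine$contexts[[i]] <- ctx
    }
    if (engine$settings$vr_display) {
      nid <- engine_next_id(engine); engine <- nid$engine
      msg <- message_packet("display", "position",
                            list(position_mm = engine$track$position_mm),
                            id = nid$id, t_ms = now_ms)
      outbox[[length(outbox) + 1L]] <- msg
    }
  }

  if (length(records) == 0L) {
    records[[1L]] <- new_record(now_ms, "heartbeat")
  }
  engine$licking <- FALSE
  list(engine = engine, outbox = outbox, records = records)
}

#' Run a complete closed-loop experiment
#'
#' Executes the three run-time phases: a setup routine that sends an
#' acknowledged synchronizing start trigger to the behavior controller
#' (so an attached recording device starts in register with the log),
#' the main event loop at the settings' step size, and a termination
#' routine that closes any open contexts and writes the stop record.
#' With the same settings, seeded rig, and fixed `wall_clock`, the
#' behavior log is byte-identical across runs.
#'
#' @param settings Settings (list, JSON path, or [validate_settings()]
#'   result).
#' @param rig A [virtual_rig()] (or compatible object).
#' @param duration_ms Experiment duration in ms.
#' @param out Path for the behavior log (`.jsonl`).
#' @param wall_clock POSIXct stored in the log header; fix it for
#'   byte-identical reruns.
#' @return The log path, invisibly, with the final engine as attribute
#'   `engine`.
#' @export
run_experiment <- function(settings, rig, duration_ms,
                           out = tempfile(fileext = ".jsonl"),
                           wall_clock = Sys.time()) {
  engine <- engine_init(settings)
  writer <- log_writer(out, wall_clock = wall_clock)
  on.exit(log_close(writer), add = TRUE)

  nid <- engine_next_id(engine); engine <- nid$engine
  sync <- message_packet("sync", "start", list(), id = nid$id, t_ms = 0)
  status <- send_with_ack(rig$behavior_transport, sync)
  if (!status$acked) {
    write_record(writer, 0, "error", list(reason = "sync trigger not acknowledged"))
    abort("synchronizing start trigger was not acknowledged by the behavior controller.",
          class = "trackloop_run_error")
  }
  write_record(writer, 0, "sync", list(action = "start", msg_id = nid$id))

  engine$running <- TRUE
  step_ms <- engine$settings$step_ms
  steps <- seq(step_ms, duration_ms, by = step_ms)
  for (now in steps) {
    inbox <- rig_poll(rig, now - step_ms, now)
    res <- engine_step(engine, now, inbox)
    engine <- res$engine
    for (m in res$outbox) rig_deliver(rig, m, now)
    for (r in res$records) {
      write_record(writer, r$t_ms, r$kind, r[setdiff(names(r), c("t_ms", "kind"))])
    }
  }

  t_end <- steps[length(steps)]
  state <- engine_state(engine)
  for (i in seq_along(engine$contexts)) {
    ctx <- engine$contexts[[i]]
    if (ctx$active) {
      for (tg in ctx$targets) {
        nid <- engine_next_id(engine); engine <- nid$engine
        msg <- message_packet(tg$route, tg$stop_action, tg$payload,
                              id = nid$id, t_ms = t_end)
        rig_deliver(rig, msg, t_end)
        write_record(writer, t_end, "message_out",
                     list(route = paste(tg$route, collapse = "/"),
                          action = tg$stop_action, msg_id = nid$id))
      }
      write_record(writer, t_end, "context_stop", list(context = ctx$id))
      ctx$active <- FALSE
      engine$contexts[[i]] <- ctx
    }
  }
  write_record(writer, t_end, "sync", list(action = "stop"))
  engine$running <- FALSE

  invisible(structure(out, engine = engine))
}
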