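#' Validate and normalize an experiment settings specification
#'
#' Settings are plain JSON key-value files (or the equivalent R list):
#'
#' ```json
#' {
#'   "track": {"track_length_mm": 2000, "scale_mm_per_tick": 0.5,
#'             "circular": true},
#'   "step_ms": 10,
#'   "contexts": [
#'     {"id": "reward", "mode": "operant",
#'      "zones": [{"center_mm": 1500, "radius_mm": 150}],
#'      "reward_duration_ms": 50},
#'     {"id": "sceneA", "decorators": [{"kind": "lap_parity", "parity": "odd"}],
#'      "targets": [{"route": ["display"], "start_action": "scene",
#'                   "payload": {"scene_id": "A"}}]}
#'   ]
#' }
#' ```
#'
#' Unknown decorator kinds, malformed zones, duplicate context ids and
#' non-positive geometry are all rejected here, at load time, never at
#' run time.
#'
#' @param x Settings list, or path to a JSON settings file.
#' @return A normalized `settings_spec`: `track` is a [track_config()],
#'   `contexts` a list of [context_list()]s, `step_ms` the event-loop
#'   step.
#' @export
validate_settings <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    x <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  }
  if (!is.list(x) || is.null(x$track)) {
    abort("settings must contain a `track` section.",
          class = "trackloop_settings_error")
  }
  tr <- x$track
  cfg <- tryCatch(
    track_config(tr$track_length_mm, tr$scale_mm_per_tick,
                 tr$circular %||% TRUE),
    error = function(e) abort(paste0("invalid track config: ", conditionMessage(e)),
                              class = "trackloop_settings_error")
  )
  ctx_defs <- x$contexts %||% list()
  contexts <- lapply(ctx_defs, function(cd) {
    if (is.null(cd$id)) abort("every context needs an `id`.",
                              class = "trackloop_settings_error")
    zones <- lapply(cd$zones %||% list(), function(z) {
      zn <- zone(z$center_mm, z$radius_mm)
      if (cfg$circular && zn$center_mm >= cfg$track_length_mm) {
        abort(sprintf("zone centre %g outside track [0, %g)",
                      zn$center_mm, cfg$track_length_mm),
              class = "trackloop_settings_error")
      }
      zn
    })
    decs <- lapply(cd$decorators %||% list(), function(d) {
      if (is.null(d$kind)) abort("decorator missing `kind`.",
                                 class = "trackloop_settings_error")
      do.call(decorator, d)
    })
    targets <- lapply(cd$targets %||% list(), function(tg) {
      list(route = as.character(unlist(tg$route)),
           start_action = tg$start_action %||% "start",
           stop_action = tg$stop_action %||% "stop",
           payload = tg$payload %||% list())
    })
    context_list(cd$id, zones = zones, decorators = decs, targets = targets,
                 mode = cd$mode %||% "none",
                 reward_duration_ms = cd$reward_duration_ms %||% 50)
  })
  ids <- vapply(contexts, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    abort("context ids must be unique.", class = "trackloop_settings_error")
  }
  structure(
    list(track = cfg, contexts = contexts,
         step_ms = as.double(x$step_ms %||% 10),
         vr_display = isTRUE(x$vr_display)),
    class = "settings_spec"
  )
}

#' Write a settings specification to JSON
#' @param settings A raw settings list (as accepted by
#'   [validate_settings()]).
#' @param path Output file path.
#' @export
write_settings <- function(settings, path) {
  jsonlite::write_json(settings, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
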