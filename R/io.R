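#' Write a neural session bundle to disk
#'
#' The on-disk session format is plain text: `frames.csv` (per-frame
#' time, position, lap), `events.csv` (per-frame rows, one column per
#' ROI, deconvolved event amplitudes), `labels.csv` (ground-truth cell
#' labels when available), and `meta.json` (frame period, track
#' geometry, seed).
#'
#' @param session A `neural_session`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session_bundle <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  frames <- tibble(t_ms = session$t_ms, position_mm = session$position_mm,
                   lap = session$lap)
  utils::write.csv(frames, file.path(dir, "frames.csv"), row.names = FALSE)
  ev <- as.data.frame(t(session$events))
  names(ev) <- sprintf("roi_%03d", seq_len(nrow(session$events)))
  utils::write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)
  if (!is.null(session$labels)) {
    utils::write.csv(session$labels, file.path(dir, "labels.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(dt = session$dt, track_length_mm = session$track_length_mm,
         circular = session$circular, seed = session$seed %||% NA),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a neural session bundle
#' @param dir Directory written by [write_session_bundle()].
#' @return A `neural_session`.
#' @export
read_session_bundle <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  frames <- utils::read.csv(file.path(dir, "frames.csv"))
  ev <- utils::read.csv(file.path(dir, "events.csv"))
  labels_path <- file.path(dir, "labels.csv")
  labels <- if (file.exists(labels_path)) {
    as_tibble(utils::read.csv(labels_path))
  }
  structure(
    list(events = t(as.matrix(ev)), position_mm = frames$position_mm,
         lap = frames$lap, t_ms = frames$t_ms, dt = meta$dt,
         track_length_mm = meta$track_length_mm,
         circular = isTRUE(meta$circular), labels = labels,
         seed = meta$seed),
    class = "neural_session"
  )
}
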