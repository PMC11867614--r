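#' Streaming behavior log writer
#'
#' The behavior file is the experiment's single source of truth: a
#' JSON-lines stream of timestamp-event pairs, appended and flushed one
#' record per line so a crash loses at most a partial final line (which
#' the reader tolerates).  The first line is a header holding the
#' wall-clock epoch; all record times are integer-ish milliseconds
#' relative to the sync start.
#'
#' @param path Output path (`.jsonl`).
#' @param wall_clock POSIXct epoch stored in the header.
#' @return A `log_writer` environment.
#' @export
log_writer <- function(path, wall_clock = Sys.time()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  env <- new.env(parent = emptyenv())
  env$con <- con
  env$path <- path
  env$last_t <- -Inf
  env$n_records <- 0L
  header <- jsonlite::toJSON(
    list(kind = "header",
         wall_clock = format(wall_clock, "%Y-%m-%dT%H:%M:%OS3%z", tz = "UTC")),
    auto_unbox = TRUE)
  writeLines(as.character(header), con)
  flush(con)
  class(env) <- "log_writer"
  env
}

#' Append one behavior record
#'
#' Record times must be non-decreasing; a record arriving with an earlier
#' timestamp is still logged, but with its time monotonized to the last
#' written time, preceded by an error record flagging the regression.
#'
#' @param writer A [log_writer()].
#' @param t_ms Record time (ms since sync start).
#' @param kind One of `"position"`, `"lap"`, `"lick"`, `"reward"`,
#'   `"context_start"`, `"context_stop"`, `"message_in"`,
#'   `"message_out"`, `"sync"`, `"error"`, `"heartbeat"`.
#' @param payload Named list of extra fields.
#' @export
write_record <- function(writer, t_ms, kind, payload = list()) {
  kinds <- c("position", "lap", "lick", "reward", "context_start",
             "context_stop", "message_in", "message_out", "sync", "error",
             "heartbeat")
  kind <- match.arg(kind, kinds)
  if (t_ms < writer$last_t) {
    err <- list(t = writer$last_t, kind = "error",
                reason = "time regression", original_t = t_ms)
    writeLines(as.character(jsonlite::toJSON(err, auto_unbox = TRUE, digits = NA)),
               writer$con)
    t_ms <- writer$last_t
  }
  rec <- c(list(t = as.double(t_ms), kind = kind), payload)
  writeLines(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE,
                                           digits = I(17), null = "null")),
             writer$con)
  flush(writer$con)
  writer$last_t <- t_ms
  writer$n_records <- writer$n_records + 1L
  invisible(writer)
}

#' Close a behavior log
#' @param writer A [log_writer()].
#' @export
log_close <- function(writer) {
  if (!is.null(writer$con)) {
    try(close(writer$con), silent = TRUE)
    writer$con <- NULL
  }
  invisible(writer$path)
}

#' Load and reconstruct a behavior session
#'
#' Parses a behavior `.jsonl` file back into analysis-ready tables: the
#' position trace, lick and reward times, paired context intervals
#' (an interval left open at the end of the file is closed at the last
#' timestamp and flagged `unclosed`), and all raw records.  A truncated
#' final line (crash artifact) is skipped with a warning; the number of
#' skipped lines is reported in `n_warnings`.
#'
#' @param path Path to a behavior log.
#' @return A `session_data` list of tibbles: `records`, `position`,
#'   `licks`, `rewards`, `laps`, `contexts`, plus `header`,
#'   `n_warnings`.
#' @export
load_session <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no behavior log at ", path), class = "trackloop_load_error")
  }
  lines <- readLines(path, warn = FALSE)
  n_warn <- 0L
  parsed <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    p <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE,
                                     simplifyDataFrame = FALSE),
                  error = function(e) NULL)
    if (is.null(p)) {
      if (i == length(lines)) {
        warn("final log line is truncated; skipped")
        n_warn <- n_warn + 1L
      } else {
        warn(sprintf("unparseable log line %d skipped", i))
        n_warn <- n_warn + 1L
      }
    }
    parsed[[i]] <- p
  }
  parsed <- parsed[!vapply(parsed, is.null, logical(1))]
  header <- NULL
  if (length(parsed) > 0 && identical(parsed[[1]]$kind, "header")) {
    header <- parsed[[1]]
    parsed <- parsed[-1]
  }
  kinds <- vapply(parsed, function(p) p$kind %||% "error", character(1))
  times <- vapply(parsed, function(p) as.double(p$t %||% NA), numeric(1))

  pick <- function(kind, fields) {
    idx <- which(kinds == kind)
    rows <- lapply(idx, function(i) {
      p <- parsed[[i]]
      vals <- lapply(fields, function(f) p[[f]] %||% NA)
      names(vals) <- fields
      as_tibble(c(list(t_ms = times[i]), vals))
    })
    if (length(rows) == 0L) {
      empty <- c(list(t_ms = double()),
                 setNames(rep(list(logical()), length(fields)), fields))
      return(as_tibble(empty))
    }
    dplyr::bind_rows(rows)
  }

  position <- pick("position", c("position_mm", "lap"))
  laps <- pick("lap", c("lap", "source", "drift_mm"))
  licks <- pick("lick", character())
  rewards <- pick("reward", c("context", "zone", "lap"))

  # pair context intervals
  ctx_idx <- which(kinds %in% c("context_start", "context_stop"))
  open <- list()
  intervals <- list()
  t_last <- if (length(times)) max(times, na.rm = TRUE) else 0
  for (i in ctx_idx) {
    p <- parsed[[i]]
    id <- p$context %||% "?"
    if (kinds[i] == "context_start") {
      open[[id]] <- times[i]
    } else {
      start <- open[[id]]
      if (!is.null(start)) {
        intervals[[length(intervals) + 1L]] <-
          tibble(context = id, start_ms = start, stop_ms = times[i],
                 unclosed = FALSE)
        open[[id]] <- NULL
      } else {
        intervals[[length(intervals) + 1L]] <-
          tibble(context = id, start_ms = NA_real_, stop_ms = times[i],
                 unclosed = FALSE)
      }
    }
  }
  for (id in names(open)) {
    if (!is.null(open[[id]])) {
      intervals[[length(intervals) + 1L]] <-
        tibble(context = id, start_ms = open[[id]], stop_ms = t_last,
               unclosed = TRUE)
    }
  }
  contexts <- if (length(intervals)) dplyr::bind_rows(intervals) else {
    tibble(context = character(), start_ms = double(), stop_ms = double(),
           unclosed = logical())
  }

  structure(
    list(
      records = tibble(t_ms = times, kind = kinds, payload = parsed),
      position = position, laps = laps, licks = licks, rewards = rewards,
      contexts = contexts, header = header, n_warnings = n_warn
    ),
    class = "session_data"
  )
}

#' Summarize a behavior log
#'
#' One-row tibble with the headline numbers of a session: duration,
#' laps, rewards, licks, context count, record count, parse warnings.
#'
#' @param path Path to a behavior log (or a loaded `session_data`).
#' @return A one-row tibble.
#' @export
inspect_session <- function(path) {
  s <- if (inherits(path, "session_data")) path else load_session(path)
  tibble(
    duration_s = if (nrow(s$records)) max(s$records$t_ms, na.rm = TRUE) / 1000 else 0,
    n_laps = if (nrow(s$laps)) max(unlist(s$laps$lap), na.rm = TRUE) else 0L,
    n_rewards = nrow(s$rewards),
    n_licks = nrow(s$licks),
    n_contexts = length(unique(s$contexts$context)),
    n_records = nrow(s$records),
    n_warnings = s$n_warnings
  )
}
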