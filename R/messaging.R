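#' Datagram message model
#'
#' Every component of the rig — position controller, behavior controller,
#' display — exchanges small JSON packets over a datagram transport.  A
#' message wraps an `action` with a `route`: an ordered list of route
#' names whose first element selects the receiving subsystem and whose
#' remainder is passed down to it.  The wire schema has top-level keys
#' `route` (array of strings), `action`, `payload`, `id` and `t_ms`
#' (milliseconds since experiment start; absent before the start signal).
#'
#' Numeric payload scalars are canonicalized to double so that a decoded
#' message compares `identical()` to the one that was encoded.
#'
#' @param route Character vector of route names, length >= 1.
#' @param action Action string, or `NULL`.
#' @param payload Named list of scalars, strings, or flat lists/vectors.
#' @param id Monotone per-sender message id (integer-valued), or `NULL`.
#' @param t_ms Timestamp in ms since experiment start, or `NULL`.
#' @return An object of class `bm_message`.
#' @examples
#' m <- message_packet("context", "start", list(id = "reward"))
#' identical(decode_message(encode_message(m)), m)
#' @export
message_packet <- function(route, action = NULL, payload = list(), id = NULL,
                           t_ms = NULL) {
  if (!is.character(route) || length(route) < 1L || anyNA(route)) {
    abort("`route` must be a non-empty character vector.", class = "trackloop_message_error")
  }
  if (!is.list(payload)) abort("`payload` must be a list.", class = "trackloop_message_error")
  if (length(payload) > 0 && (is.null(names(payload)) || any(names(payload) == ""))) {
    abort("`payload` entries must all be named.", class = "trackloop_message_error")
  }
  structure(
    list(
      route = as.character(route),
      action = if (!is.null(action)) as.character(action)[1],
      payload = canonicalize_payload(payload),
      id = if (!is.null(id)) as.double(id),
      t_ms = if (!is.null(t_ms)) as.double(t_ms)
    ),
    class = "bm_message"
  )
}

#' @export
print.bm_message <- function(x, ...) {
  cat("<message> route:", paste(x$route, collapse = "/"),
      if (!is.null(x$action)) paste0(" action: ", x$action),
      if (!is.null(x$id)) paste0(" id: ", x$id),
      if (!is.null(x$t_ms)) paste0(" t: ", x$t_ms, "ms"), "\n")
  invisible(x)
}

# Integers (from user input or the JSON parser) become doubles; lists are
# canonicalized recursively.  NULLs and unserializable objects error.
canonicalize_payload <- function(x) {
  canon1 <- function(v) {
    if (is.integer(v)) return(as.double(v))
    if (is.list(v)) return(lapply(v, canon1))
    if (is.numeric(v) || is.character(v) || is.logical(v)) return(v)
    abort(
      paste0("payload value of class <", paste(class(v), collapse = "/"),
             "> is not serializable"),
      class = "trackloop_encode_error"
    )
  }
  lapply(x, canon1)
}

#' Encode a message as one JSON datagram
#'
#' Serializes to a single UTF-8 JSON object small enough for one MTU
#' (1400 bytes); larger messages are rejected at encode time rather than
#' risking fragmentation.
#'
#' @param m A [message_packet()].
#' @param max_bytes Datagram size limit in bytes.
#' @return A raw vector.
#' @export
encode_message <- function(m, max_bytes = 1400L) {
  if (!inherits(m, "bm_message")) {
    m <- message_packet(m$route, m$action, m$payload %||% list(), m$id, m$t_ms)
  }
  body <- list(route = I(m$route))
  if (!is.null(m$action)) body$action <- m$action
  body$payload <- m$payload
  if (!is.null(m$id)) body$id <- m$id
  if (!is.null(m$t_ms)) body$t_ms <- m$t_ms
  # I(17) significant digits: doubles survive the round trip bit-exactly
  json <- jsonlite::toJSON(body, auto_unbox = TRUE, digits = I(17),
                           null = "null")
  out <- charToRaw(as.character(json))
  if (length(out) > max_bytes) {
    abort(
      paste0("encoded message is ", length(out), " bytes; limit ", max_bytes),
      class = "trackloop_encode_error"
    )
  }
  out
}

#' Decode a JSON datagram into a message
#'
#' Malformed JSON raises a structured parse error that carries the raw
#' bytes (so a receiver can dead-letter them); unknown top-level keys are
#' preserved inside the payload.
#'
#' @param b Raw vector or single string.
#' @return A [message_packet()].
#' @export
decode_message <- function(b) {
  txt <- if (is.raw(b)) rawToChar(b) else as.character(b)
  parsed <- tryCatch(
    jsonlite::fromJSON(txt, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE),
    error = function(e) {
      abort(paste0("malformed datagram: ", conditionMessage(e)),
            class = "trackloop_parse_error", raw_bytes = b)
    }
  )
  if (!is.list(parsed) || is.null(parsed$route)) {
    abort("datagram is valid JSON but not a routed message",
          class = "trackloop_parse_error", raw_bytes = b)
  }
  known <- c("route", "action", "payload", "id", "t_ms")
  extra <- parsed[setdiff(names(parsed), known)]
  payload <- c(as.list(parsed$payload), extra)
  message_packet(
    route = unlist(parsed$route),
    action = parsed$action,
    payload = payload,
    id = parsed$id,
    t_ms = parsed$t_ms
  )
}

#' Network endpoint for a rig device
#'
#' Each device on the rig's private network has a statically assigned
#' address; `(host, port)` pairs must be unique within a registry.
#'
#' @param host Network address string (default loopback).
#' @param port Integer port in `[1, 65535]`.
#' @return An `endpoint` record.
#' @export
endpoint <- function(host = "127.0.0.1", port) {
  port <- as.integer(port)
  if (is.na(port) || port < 1L || port > 65535L) {
    abort("`port` must be in [1, 65535].", class = "trackloop_message_error")
  }
  structure(list(host = as.character(host), port = port), class = "endpoint")
}

#' Route a message to a handler registry
#'
#' The first route element selects the handler; the remaining elements are
#' passed down as the sub-route.  A message whose head route has no
#' handler is never an error: it is recorded as a dead letter and the
#' caller decides what to do with it (messages in == handled +
#' dead-lettered).
#'
#' @param m A [message_packet()].
#' @param registry Named list of handler functions `f(m, subroute)`.
#' @return `list(result =, dead_letter = NULL | tibble row)`.
#' @export
dispatch <- function(m, registry) {
  stopifnot(is.list(registry), length(registry) > 0)
  head <- m$route[[1]]
  if (!is.null(registry[[head]])) {
    sub <- if (length(m$route) > 1L) m$route[-1] else character()
    list(result = registry[[head]](m, sub), dead_letter = NULL)
  } else {
    list(result = NULL, dead_letter = tibble(
      route = paste(m$route, collapse = "/"),
      action = m$action %||% NA_character_,
      reason = "unmatched route"
    ))
  }
}

#' Acknowledged datagram delivery
#'
#' Sends a message over a (possibly lossy) transport and waits for an
#' acknowledgment packet `{route: ["ack"], payload: {id: <msg_id>}}`.
#' Retries resend the identical `msg_id` so receivers can deduplicate;
#' exactly `min(needed, 1 + max_retries)` sends occur.
#'
#' @param transport A transport object (see [transport_lossless()]).
#' @param m Message to deliver; must carry an `id`.
#' @param timeout_ms Ack timeout per try (bookkeeping only for scripted
#'   in-process transports, which reply synchronously).
#' @param max_retries Number of resends after the first try.
#' @return A tibble with columns `acked` (logical), `sends` (integer),
#'   `msg_id`.
#' @export
send_with_ack <- function(transport, m, timeout_ms = 100, max_retries = 3L) {
  stopifnot(timeout_ms > 0, max_retries >= 0)
  if (is.null(m$id)) abort("message must carry an `id` for acknowledged delivery.",
                           class = "trackloop_message_error")
  bytes <- encode_message(m)
  tries <- 1L + as.integer(max_retries)
  for (k in seq_len(tries)) {
    reply <- transport_send(transport, bytes)
    if (!is.null(reply)) {
      ack <- decode_message(reply)
      if (identical(ack$route[[1]], "ack") &&
          isTRUE(ack$payload$id == m$id)) {
        return(tibble(acked = TRUE, sends = k, msg_id = m$id))
      }
    }
  }
  tibble(acked = FALSE, sends = tries, msg_id = m$id)
}

#' Build an acknowledgment packet for a message id
#' @param msg_id The id being acknowledged.
#' @export
ack_packet <- function(msg_id) {
  message_packet("ack", payload = list(id = as.double(msg_id)))
}
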