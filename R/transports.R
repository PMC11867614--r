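#' Scripted in-process transports
#'
#' All tests and simulated sessions run without a network: a transport is
#' an environment with a `deliver(bytes)` function connecting the sender
#' to a peer (a function taking raw datagram bytes and returning raw
#' reply bytes, or `NULL` for no reply).  Three scripted variants cover
#' the behaviors needed for delivery testing: lossless, a drop list
#' (drops the n-th outgoing datagrams), and a fixed delay.
#'
#' @param peer Function `f(bytes) -> raw reply | NULL`.
#' @return A transport object.
#' @name transports
NULL

#' @rdname transports
#' @export
transport_lossless <- function(peer) {
  env <- new.env(parent = emptyenv())
  env$peer <- peer
  env$sent <- 0L
  env$delay_ms <- 0
  env$drop <- integer()
  class(env) <- "bm_transport"
  env
}

#' @rdname transports
#' @param drop Integer indices of outgoing datagrams to drop (1-based,
#'   counted over the lifetime of the transport).
#' @export
transport_droplist <- function(peer, drop) {
  env <- transport_lossless(peer)
  env$drop <- as.integer(drop)
  env
}

#' @rdname transports
#' @param delay_ms One-way delivery delay recorded for each datagram.
#' @export
transport_fixed_delay <- function(peer, delay_ms) {
  env <- transport_lossless(peer)
  env$delay_ms <- as.double(delay_ms)
  env
}

# Deliver one datagram; returns the peer's raw reply or NULL if this
# datagram (or everything, drop = Inf sentinel via large indices) is lost.
transport_send <- function(transport, bytes) {
  transport$sent <- transport$sent + 1L
  if (transport$sent %in% transport$drop) return(NULL)
  transport$peer(bytes)
}

#' A deduplicating message sink peer
#'
#' Builds a peer function for scripted transports that applies a handler
#' once per distinct message id (duplicate deliveries are idempotent) and
#' always acknowledges.  Used by the virtual devices.
#'
#' @param handler Function called as `handler(message)` for each new id.
#' @return A peer function suitable for [transport_lossless()], with the
#'   environment fields `seen_ids` and `n_handled` for inspection.
#' @export
ack_peer <- function(handler = function(m) NULL) {
  seen <- new.env(parent = emptyenv())
  seen$ids <- numeric()
  seen$n_handled <- 0L
  f <- function(bytes) {
    m <- decode_message(bytes)
    if (is.null(m$id) || !(m$id %in% seen$ids)) {
      handler(m)
      seen$n_handled <- seen$n_handled + 1L
      if (!is.null(m$id)) seen$ids <- c(seen$ids, m$id)
    }
    encode_message(ack_packet(m$id %||% -1))
  }
  attr(f, "state") <- seen
  f
}
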