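#' Circular distance between track positions
#'
#' Shortest-arc distance between two positions on a circular track of
#' length `L`, in the same units as the inputs.  Used everywhere a
#' circular track is configured: zone tests, decoding error, chance
#' levels, lap-reset drift.
#'
#' @param a,b Numeric vectors of positions (recycled).
#' @param L Track length (same units as `a` and `b`).
#' @return Numeric vector of distances in `[0, L/2]`.
#' @examples
#' circular_distance(5, 1995, L = 2000) # 10, wraps around 0
#' @export
circular_distance <- function(a, b, L) {
  d <- abs(a - b) %% L
  pmin(d, L - d)
}

#' Signed shortest-arc displacement from b to a on a circular track.
#' Result lies in (-L/2, L/2].
#' @noRd
circular_signed <- function(a, b, L) {
  d <- (a - b) %% L
  ifelse(d > L / 2, d - L, d)
}

# Derive a reproducible sub-seed for a named random substream, kept
# within 32-bit integer range.
substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k * 101) %% (.Machine$integer.max - 1L)) + 1L
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
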