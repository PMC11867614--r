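#' Plot a tuning curve
#'
#' Raw and smoothed per-bin event rates, with an optional shuffle
#' threshold overlay.
#'
#' @param object A [compute_tuning()] result.
#' @param threshold Optional [shuffle_threshold()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tuning_curve <- function(object, threshold = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$center_mm / 10)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$rate), fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$rate_smooth), linewidth = 0.8) +
    ggplot2::labs(x = "position (cm)", y = "event rate (events/s)")
  if (!is.null(threshold)) {
    thr <- dplyr::left_join(as_tibble(object)[, c("bin", "center_mm")],
                            threshold, by = "bin")
    p <- p + ggplot2::geom_line(
      data = thr,
      ggplot2::aes(y = .data$threshold), linetype = "dashed", colour = "red")
  }
  p
}

#' Place-field heat map of a population
#'
#' Peak-normalized smoothed tuning curves of the place cells, sorted by
#' field position — the standard tiling figure.
#'
#' @param session A `neural_session`.
#' @param scan Optional [classify_place_cells()] result; all cells are
#'   shown when omitted.
#' @param bin_cm,smooth_sd_bins Tuning parameters.
#' @return A ggplot.
#' @export
plot_place_field_map <- function(session, scan = NULL, bin_cm = 4,
                                 smooth_sd_bins = 2) {
  pop <- population_tuning(session, bin_cm, smooth_sd_bins)
  keep <- if (!is.null(scan)) which(scan$is_place_cell) else seq_len(nrow(pop))
  pop <- pop[keep, , drop = FALSE]
  peak <- apply(pop, 1, max)
  pop <- pop / pmax(peak, .Machine$double.eps)
  ord <- order(apply(pop, 1, which.max))
  sorted <- pop[ord, , drop = FALSE]
  df <- tibble(
    row = rep(seq_len(nrow(sorted)), times = ncol(sorted)),
    bin = rep(seq_len(ncol(sorted)), each = nrow(sorted)),
    rate = as.vector(sorted)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin * bin_cm, y = .data$row,
                                   fill = .data$rate)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "norm. rate") +
    ggplot2::labs(x = "position (cm)", y = "cell (sorted by field)")
}

#' Plot decoded versus true position
#'
#' @param decoded_bins,true_bins Integer bin vectors.
#' @param bin_cm Bin width (cm).
#' @param t_s Optional frame times (s).
#' @return A ggplot.
#' @export
plot_decoding <- function(decoded_bins, true_bins, bin_cm = 4, t_s = NULL) {
  t_s <- t_s %||% seq_along(true_bins)
  df <- tibble(
    t = rep(t_s, 2),
    position_cm = c(true_bins, decoded_bins) * bin_cm,
    trace = rep(c("true", "decoded"), each = length(true_bins))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$position_cm,
                                   colour = .data$trace)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::labs(x = "time", y = "position (cm)", colour = NULL)
}

#' Plot a behavior session
#'
#' Position trace with lick and reward events overlaid, straight from a
#' loaded behavior log.
#'
#' @param object A [load_session()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.session_data <- function(object, ...) {
  pos <- object$position
  p <- ggplot2::ggplot(pos, ggplot2::aes(.data$t_ms / 1000,
                                         .data$position_mm / 10)) +
    ggplot2::geom_line(colour = "grey40", linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "position (cm)")
  if (nrow(object$licks)) {
    lk <- object$licks
    lk$position_cm <- stats::approx(pos$t_ms, pos$position_mm / 10,
                                    lk$t_ms, rule = 2)$y
    p <- p + ggplot2::geom_point(data = lk,
      ggplot2::aes(.data$t_ms / 1000, .data$position_cm),
      colour = "steelblue", size = 0.5)
  }
  if (nrow(object$rewards)) {
    rw <- object$rewards
    rw$position_cm <- stats::approx(pos$t_ms, pos$position_mm / 10,
                                    rw$t_ms, rule = 2)$y
    p <- p + ggplot2::geom_point(data = rw,
      ggplot2::aes(.data$t_ms / 1000, .data$position_cm),
      colour = "red", shape = 17, size = 1.5)
  }
  p
}
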