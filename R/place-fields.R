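# per-lap x bin matrix of binarized event counts
lap_bin_events <- function(events, position_mm, lap, track_length_mm,
                           bin_cm = 4) {
  B <- max(1L, round(track_length_mm / (bin_cm * 10)))
  laps <- sort(unique(lap))
  bins <- position_bins(position_mm, track_length_mm, bin_cm)
  M <- matrix(0L, length(laps), B, dimnames = list(laps, NULL))
  ev <- which(events > 0)
  if (length(ev)) {
    li <- match(lap[ev], laps)
    idx <- cbind(li, bins[ev])
    for (r in seq_along(ev)) M[idx[r, 1], idx[r, 2]] <- M[idx[r, 1], idx[r, 2]] + 1L
  }
  M
}

#' Per-bin significance threshold by circular trial shuffling
#'
#' The null for spatial tuning: event times are circularly shifted
#' relative to position independently within each lap (trial) by a
#' uniform random offset, the tuning curve is recomputed, and the
#' per-bin 99th percentile over `n_shuffles` surrogate curves is the
#' significance threshold.  Occupancy is untouched by the shuffle, so
#' the null preserves each cell's event count and each lap's coverage.
#'
#' @param events Per-frame event train.
#' @param position_mm,lap Per-frame position (mm) and lap index.
#' @param dt Frame period (s).
#' @param track_length_mm Track length (mm).
#' @param n_shuffles Number of surrogate curves (1000 by default).
#' @param percentile Threshold percentile (99 by default).
#' @param bin_cm,smooth_sd_bins,circular As in [compute_tuning()].
#' @param seed Integer seed; identical seeds give identical thresholds.
#' @return A tibble `bin`, `threshold`; attribute `shuffle_curves` holds
#'   the B x n_shuffles surrogate matrix when `keep_curves = TRUE`.
#' @param keep_curves Keep the full surrogate matrix?
#' @export
shuffle_threshold <- function(events, position_mm, lap, dt, track_length_mm,
                              n_shuffles = 1000, percentile = 99,
                              bin_cm = 4, smooth_sd_bins = 2, circular = TRUE,
                              seed = 1L, keep_curves = FALSE) {
  laps <- unique(lap)
  if (length(laps) < 2L) {
    abort("need at least 2 laps for the trial shuffle.",
          class = "trackloop_analysis_error")
  }
  B <- max(1L, round(track_length_mm / (bin_cm * 10)))
  bins <- position_bins(position_mm, track_length_mm, bin_cm)
  dwell <- tabulate(bins, B) * dt
  set.seed(seed)
  counts <- matrix(0, B, n_shuffles)
  for (l in laps) {
    fr <- which(lap == l)
    len <- length(fr)
    ev_w <- which(events[fr] > 0) - 1L # within-lap offsets, 0-based
    offs <- sample.int(len, n_shuffles, replace = TRUE) - 1L
    if (length(ev_w) == 0L) next
    idx <- (outer(ev_w, offs, "+") %% len) + 1L      # n_e x S within-lap frame
    b <- matrix(bins[fr][idx], nrow = length(ev_w))  # n_e x S bins
    flat <- as.vector(b) + B * rep(0:(n_shuffles - 1L), each = length(ev_w))
    counts <- counts + matrix(tabulate(flat, B * n_shuffles), B, n_shuffles)
  }
  rates <- counts / pmax(dwell, .Machine$double.eps)
  rates[dwell == 0, ] <- 0
  K <- smoothing_kernel(B, smooth_sd_bins, circular)
  sm <- K %*% rates
  thr <- apply(sm, 1, quantile, probs = percentile / 100, names = FALSE)
  out <- tibble(bin = seq_len(B), threshold = as.numeric(thr))
  if (keep_curves) attr(out, "shuffle_curves") <- sm
  out
}

#' Detect place fields in a tuning curve
#'
#' Candidate fields are maximal runs of bins whose smoothed rate exceeds
#' the per-bin shuffle threshold (runs may wrap on circular tracks).  A
#' run is a field only if it spans at least `min_bins` (3 bins = 12 cm)
#' and fewer than `max_bins` (25 bins = 100 cm) consecutive bins, and —
#' to guard against spurious bins — binarized events occurred within the
#' run's bins on at least `min_lap_frac` (50%) of laps.  A cell with at
#' least one surviving field is a place cell.
#'
#' @param curve A [compute_tuning()] result (or a numeric rate vector).
#' @param threshold A [shuffle_threshold()] result (or numeric vector).
#' @param events_by_lap Laps x bins binarized-event count matrix (see
#'   the session helpers), used for the trial-reliability rule.
#' @param min_bins Minimum run length in bins (inclusive).
#' @param max_bins Maximum run length in bins (exclusive).
#' @param min_lap_frac Minimum fraction of laps with an in-run event.
#' @param circular Allow runs to wrap around the track ends?
#' @return A tibble of fields: `start_bin`, `end_bin` (inclusive,
#'   possibly < start when wrapping), `width_bins`, `peak_bin`,
#'   `peak_rate`, `lap_fraction`.  Zero rows when the cell has no field.
#' @export
detect_place_fields <- function(curve, threshold, events_by_lap,
                                min_bins = 3L, max_bins = 25L,
                                min_lap_frac = 0.5, circular = TRUE) {
  rate <- if (is.data.frame(curve)) curve$rate_smooth else as.numeric(curve)
  thr <- if (is.data.frame(threshold)) threshold$threshold else as.numeric(threshold)
  B <- length(rate)
  stopifnot(length(thr) == B, ncol(events_by_lap) == B)
  sig <- rate > thr

  empty <- tibble(start_bin = integer(), end_bin = integer(),
                  width_bins = integer(), peak_bin = integer(),
                  peak_rate = numeric(), lap_fraction = numeric())
  if (!any(sig)) return(empty)

  if (all(sig)) {
    runs <- list(seq_len(B))
  } else {
    # rotate so the sequence starts at a non-significant bin, then rle
    start <- if (circular) which(!sig)[1] else 1L
    ord <- ((seq_len(B) + start - 2L) %% B) + 1L
    if (!circular) ord <- seq_len(B)
    r <- rle(sig[ord])
    ends <- cumsum(r$lengths)
    begins <- ends - r$lengths + 1L
    runs <- lapply(which(r$values), function(j) ord[begins[j]:ends[j]])
  }

  rows <- lapply(runs, function(bins_in_run) {
    w <- length(bins_in_run)
    if (w < min_bins || w >= max_bins) return(NULL)
    in_run <- rowSums(events_by_lap[, bins_in_run, drop = FALSE]) > 0
    frac <- mean(in_run)
    if (frac < min_lap_frac) return(NULL)
    pk <- bins_in_run[which.max(rate[bins_in_run])]
    tibble(start_bin = bins_in_run[1], end_bin = bins_in_run[w],
           width_bins = w, peak_bin = pk, peak_rate = rate[pk],
           lap_fraction = frac)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  dplyr::bind_rows(rows)
}

# bins covered by a field row (handles wrapping)
field_bins <- function(field, B) {
  s <- field$start_bin; e <- field$end_bin
  if (e >= s) s:e else c(s:B, 1:e)
}

#' Place-field sensitivity of a cell
#'
#' The fraction of laps on which at least one binarized event fell
#' inside the detected field.  With multiple fields the value is
#' computed per field and averaged, giving one number per cell.
#'
#' @param fields A [detect_place_fields()] tibble (>= 1 row).
#' @param events_by_lap Laps x bins binarized-event count matrix.
#' @return Fraction in `[0, 1]`.
#' @export
field_sensitivity <- function(fields, events_by_lap) {
  stopifnot(nrow(fields) >= 1L)
  B <- ncol(events_by_lap)
  per_field <- vapply(seq_len(nrow(fields)), function(i) {
    bins <- field_bins(fields[i, ], B)
    mean(rowSums(events_by_lap[, bins, drop = FALSE]) > 0)
  }, numeric(1))
  mean(per_field)
}

#' Place-field specificity of a cell
#'
#' Per lap, the fraction of that lap's events falling inside the field,
#' averaged across laps that had at least one event; per field, then
#' averaged across fields for one value per cell.
#'
#' @inheritParams field_sensitivity
#' @return Fraction in `[0, 1]`, or `NA` with a warning when no lap has
#'   any event.
#' @export
field_specificity <- function(fields, events_by_lap) {
  stopifnot(nrow(fields) >= 1L)
  B <- ncol(events_by_lap)
  totals <- rowSums(events_by_lap)
  has_ev <- totals > 0
  if (!any(has_ev)) {
    warn("no lap has any event; specificity undefined")
    return(NA_real_)
  }
  per_field <- vapply(seq_len(nrow(fields)), function(i) {
    bins <- field_bins(fields[i, ], B)
    in_field <- rowSums(events_by_lap[, bins, drop = FALSE])
    mean(in_field[has_ev] / totals[has_ev])
  }, numeric(1))
  mean(per_field)
}

#' Two-proportion z-test
#'
#' Pooled-variance two-sample test for a difference between two
#' proportions (e.g. the fraction of recorded cells classified as place
#' cells in two environments):
#' \deqn{z = (\hat p_2 - \hat p_1) / \sqrt{\hat p (1 - \hat p)
#'       (1/n_1 + 1/n_2)}}
#' with \eqn{\hat p} the pooled proportion.
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @return A one-row tibble: `estimate1`, `estimate2`, `statistic`
#'   (|z|), `p_value` (two-sided normal).
#' @examples
#' two_proportion_ztest(3253, 9195, 6101, 13454)
#' @export
two_proportion_ztest <- function(k1, n1, k2, n2) {
  stopifnot(k1 >= 0, k2 >= 0, n1 > 0, n2 > 0, k1 <= n1, k2 <= n2)
  p1 <- k1 / n1
  p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  if (pp == 0 || pp == 1) {
    warn("pooled proportion is degenerate (0 or 1)")
    return(tibble(estimate1 = p1, estimate2 = p2,
                  statistic = NA_real_, p_value = NA_real_))
  }
  z <- (p2 - p1) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  tibble(estimate1 = p1, estimate2 = p2, statistic = abs(z),
         p_value = 2 * pnorm(-abs(z)))
}
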