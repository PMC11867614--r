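#' Binarize a deconvolved event-amplitude train
#'
#' Deconvolution of a fluorescence trace yields an event-amplitude train;
#' small amplitudes are noise.  Events are kept only when their amplitude
#' exceeds `median(raw) + k * MAD(raw)` computed on the raw trace, with
#' an unscaled MAD (no normal-consistency factor) and `k = 4` by
#' default.  A constant raw trace has MAD 0; all nonzero events are then
#' retained with a warning.
#'
#' @param amplitude Numeric vector of deconvolved event amplitudes.
#' @param raw Numeric raw trace of the same length (used for the
#'   threshold only).
#' @param k Threshold in MADs above the median.
#' @param mad_constant Consistency constant passed to [stats::mad()];
#'   1 (unscaled) by default.
#' @return The amplitude train with sub-threshold entries zeroed.
#' @export
binarize_events <- function(amplitude, raw, k = 4, mad_constant = 1) {
  stopifnot(length(amplitude) == length(raw))
  m <- stats::mad(raw, constant = mad_constant)
  if (m == 0) {
    warn("raw trace has zero MAD; retaining all nonzero events")
    return(ifelse(amplitude > 0, amplitude, 0))
  }
  thr <- median(raw) + k * m
  ifelse(amplitude > thr, amplitude, 0)
}

#' Select significant fluorescence transients
#'
#' Masks samples more than `k` standard deviations above the mean of the
#' trace.  Used only for amplitude / frequency summaries of significant
#' transients, not for place-field detection.
#'
#' @param dff Numeric \eqn{\Delta F/F} trace.
#' @param k SD threshold.
#' @return Logical mask.
#' @export
select_significant_transients <- function(dff, k = 3) {
  stopifnot(all(is.finite(dff)))
  dff > mean(dff) + k * sd(dff)
}

# frame -> spatial bin index (1..B) for 4 cm (default) bins
position_bins <- function(position_mm, track_length_mm, bin_cm = 4) {
  B <- max(1L, round(track_length_mm / (bin_cm * 10)))
  bin <- floor(position_mm / (track_length_mm / B)) + 1L
  pmin(pmax(bin, 1L), B)
}

# circular (or truncated) Gaussian smoothing matrix, rows normalized,
# truncation at 4 SD
smoothing_kernel <- function(B, sd_bins = 2, circular = TRUE, trunc_sd = 4) {
  if (sd_bins <= 0) return(diag(B))
  K <- matrix(0, B, B)
  for (i in seq_len(B)) {
    d <- abs(seq_len(B) - i)
    if (circular) d <- pmin(d, B - d)
    w <- exp(-d^2 / (2 * sd_bins^2))
    w[d > trunc_sd * sd_bins] <- 0
    K[i, ] <- w / sum(w)
  }
  K
}

#' Spatial occupancy map
#'
#' Dwell time per spatial bin and the occupancy probability
#' `p = dwell / sum(dwell)`, with the track divided into bins of
#' `bin_cm` (4 cm by default).
#'
#' @param position_mm Per-frame position trace (mm).
#' @param dt Frame period (s).
#' @param track_length_mm Track length (mm).
#' @param bin_cm Bin width (cm).
#' @return A tibble with columns `bin`, `center_mm`, `dwell_s`, `p`.
#' @export
compute_occupancy <- function(position_mm, dt, track_length_mm, bin_cm = 4) {
  B <- max(1L, round(track_length_mm / (bin_cm * 10)))
  bins <- position_bins(position_mm, track_length_mm, bin_cm)
  dwell <- tabulate(bins, B) * dt
  if (sum(dwell) == 0) {
    abort("occupancy is zero everywhere.", class = "trackloop_analysis_error")
  }
  tibble(
    bin = seq_len(B),
    center_mm = (seq_len(B) - 0.5) * track_length_mm / B,
    dwell_s = dwell,
    p = dwell / sum(dwell)
  )
}

#' Occupancy-normalized tuning curve
#'
#' Binarized events are counted per 4 cm spatial bin, divided by dwell
#' time to give an event rate, and smoothed with a Gaussian filter
#' (SD = 2 bins by default) that wraps circularly on circular tracks.
#' Bins never visited get rate 0 and are flagged.
#'
#' @param events Per-frame event train (amplitudes; any value > 0 counts
#'   as one event).
#' @param position_mm Per-frame position (mm), same length.
#' @param dt Frame period (s).
#' @param track_length_mm Track length (mm).
#' @param bin_cm Spatial bin width (cm).
#' @param smooth_sd_bins Gaussian smoothing SD, in bins.
#' @param circular Wrap the smoothing around the track ends?
#' @return A `tuning_curve` tibble: `bin`, `center_mm`, `dwell_s`, `p`,
#'   `n_events`, `rate`, `rate_smooth`, `visited`; attribute
#'   `mean_rate` is the occupancy-weighted mean of the smoothed rate.
#' @export
compute_tuning <- function(events, position_mm, dt, track_length_mm,
                           bin_cm = 4, smooth_sd_bins = 2, circular = TRUE) {
  stopifnot(length(events) == length(position_mm))
  occ <- compute_occupancy(position_mm, dt, track_length_mm, bin_cm)
  B <- nrow(occ)
  bins <- position_bins(position_mm, track_length_mm, bin_cm)
  counts <- tabulate(bins[events > 0], B)
  rate <- ifelse(occ$dwell_s > 0, counts / pmax(occ$dwell_s, .Machine$double.eps), 0)
  K <- smoothing_kernel(B, smooth_sd_bins, circular)
  rate_smooth <- as.numeric(K %*% rate)
  out <- occ
  out$n_events <- counts
  out$rate <- rate
  out$rate_smooth <- rate_smooth
  out$visited <- occ$dwell_s > 0
  attr(out, "mean_rate") <- sum(occ$p * rate_smooth)
  class(out) <- c("tuning_curve", class(out))
  out
}

#' Spatial information of a tuning curve
#'
#' Information carried by one event about the animal's position,
#' \deqn{SI = \sum_i p_i \frac{\lambda_i}{\bar\lambda}
#'       \log_2 \frac{\lambda_i}{\bar\lambda}}
#' with occupancy probabilities \eqn{p_i}, per-bin rates
#' \eqn{\lambda_i}, and mean rate
#' \eqn{\bar\lambda = \sum_i p_i \lambda_i}.  Zero-rate bins contribute
#' 0.  A flat curve gives 0 bits/event; all activity concentrated in one
#' of B equally occupied bins gives log2(B).
#'
#' @param rate Per-bin event rates (use the smoothed curve for the
#'   standard metric).
#' @param p Occupancy probabilities (must sum to 1).
#' @return Spatial information in bits per event; `NA` with a warning if
#'   the mean rate is 0.
#' @export
spatial_information <- function(rate, p) {
  stopifnot(length(rate) == length(p))
  lambda_bar <- sum(p * rate)
  if (lambda_bar <= 0) {
    warn("mean rate is zero; spatial information undefined")
    return(NA_real_)
  }
  ratio <- rate / lambda_bar
  terms <- ifelse(rate > 0, p * ratio * log2(ratio), 0)
  sum(terms)
}

#' Rate-map correlation between two tuning curves
#'
#' Pearson correlation between per-bin rates of the same cell in two
#' contexts; the standard remapping statistic.
#'
#' @param a,b Numeric per-bin rate vectors of equal length.
#' @return Pearson r, or `NA` with a warning when either curve has zero
#'   variance.
#' @export
rate_map_correlation <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (sd(a) == 0 || sd(b) == 0) {
    warn("zero-variance tuning curve; correlation undefined")
    return(NA_real_)
  }
  cor(a, b)
}

#' Optimal circular population-vector shift
#'
#' On a belt, place fields may anchor to the belt seam, so two sessions
#' can differ by a global rotation.  For every candidate shift the
#' population vectors (the across-cell activity at each bin) of the two
#' sessions are correlated bin by bin and averaged; the shift maximizing
#' the mean correlation is returned (ties break to the smallest shift).
#' Applying the returned shift to `popB`'s columns aligns it to `popA`.
#'
#' @param popA,popB Matrices of cells x bins average rates, equal sizes.
#' @return A list: `shift` (bins, in `[0, B)`), `mean_correlation`, and
#'   `by_shift` (tibble of all candidates).
#' @export
optimal_circular_shift <- function(popA, popB) {
  stopifnot(all(dim(popA) == dim(popB)))
  B <- ncol(popA)
  mean_cor <- vapply(0:(B - 1), function(s) {
    shifted <- popB[, ((seq_len(B) - 1 + s) %% B) + 1, drop = FALSE]
    cors <- vapply(seq_len(B), function(b) {
      x <- popA[, b]; y <- shifted[, b]
      if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
    }, numeric(1))
    mean(cors, na.rm = TRUE)
  }, numeric(1))
  best <- which.max(mean_cor)  # which.max returns the first (smallest shift)
  list(
    shift = best - 1L,
    mean_correlation = mean_cor[best],
    by_shift = tibble(shift = 0:(B - 1), mean_correlation = mean_cor)
  )
}

# rotate columns of a cells x bins matrix forward by s bins, so that
# optimal_circular_shift(pop, rotate_population(pop, s))$shift == s
rotate_population <- function(pop, s) {
  B <- ncol(pop)
  pop[, ((seq_len(B) - 1 - s) %% B) + 1, drop = FALSE]
}
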