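#' Fit a naive-Bayes position decoder
#'
#' The decoder model is the cells x bins matrix `f[i, pos]`: the average
#' binarized activity of cell `i` in spatial bin `pos` over the training
#' frames, floored at `eps` so the log-likelihood stays finite, plus the
#' decoding window `tau` in seconds (one frame period by default).
#'
#' @param events Cells x frames matrix of binarized event trains (any
#'   value > 0 counts as activity 1 on that frame).
#' @param position_mm Per-frame position (mm).
#' @param train_frames Integer indices of the training frames.
#' @param dt Frame period (s).
#' @param track_length_mm Track length (mm).
#' @param bin_cm Spatial bin width (cm).
#' @param tau Decoding window (s); defaults to `dt`.
#' @param eps Floor on `f` (events/frame).
#' @param circular Is the track circular?
#' @return A `decoder_model`: `f` (cells x bins), `tau`, `bin_centers_mm`,
#'   `empty_bins` (bins with no training occupancy, flagged).
#' @export
fit_decoder <- function(events, position_mm, train_frames, dt,
                        track_length_mm, bin_cm = 4, tau = dt, eps = 1e-4,
                        circular = TRUE) {
  events <- as.matrix(events)
  stopifnot(ncol(events) == length(position_mm))
  B <- max(1L, round(track_length_mm / (bin_cm * 10)))
  bins <- position_bins(position_mm, track_length_mm, bin_cm)[train_frames]
  act <- (events[, train_frames, drop = FALSE] > 0) * 1
  n_per_bin <- tabulate(bins, B)
  sums <- matrix(0, nrow(events), B)
  present <- sort(unique(bins))
  agg <- rowsum(t(act), group = bins) # bins-present x cells
  sums[, present] <- t(agg)
  f <- sweep(sums, 2, pmax(n_per_bin, 1L), "/")
  empty <- which(n_per_bin == 0L)
  f_raw <- f
  f <- pmax(f, eps)
  structure(
    list(f = f, f_raw = f_raw, tau = tau,
         bin_centers_mm = (seq_len(B) - 0.5) * track_length_mm / B,
         track_length_mm = track_length_mm, bin_cm = bin_cm,
         circular = circular, empty_bins = empty, dt = dt),
    class = "decoder_model"
  )
}

#' Posterior position distribution for one frame
#'
#' The naive-Bayes posterior over spatial bins given the population
#' activity vector `a`:
#' \deqn{P(pos \mid a) = C \left(\prod_i f_i(pos)^{a_i}\right)
#'       e^{-\tau \sum_i f_i(pos)}}
#' computed in log space and normalized so the probabilities sum to 1.
#' The decoded bin is the argmax (ties break to the lowest bin index).
#'
#' @param a Activity vector, length = number of cells (binarized event
#'   indicators, or counts within the decoding window).
#' @param model A [fit_decoder()] model.
#' @return A numeric probability vector over bins, with attribute
#'   `decoded_bin`.
#' @export
decode_posterior <- function(a, model) {
  stopifnot(length(a) == nrow(model$f), all(a >= 0))
  logf <- log(model$f)
  logpost <- as.numeric(crossprod(logf, a)) - model$tau * colSums(model$f)
  logpost <- logpost - max(logpost)
  p <- exp(logpost)
  p <- p / sum(p)
  attr(p, "decoded_bin") <- which.max(p) # first max = lowest index
  p
}

# decode many frames at once; returns integer decoded bins
decode_frames <- function(events, frames, model) {
  A <- (as.matrix(events)[, frames, drop = FALSE] > 0) * 1
  logf <- log(model$f)                       # N x B
  LP <- crossprod(logf, A)                   # B x T
  LP <- LP - model$tau * colSums(model$f)
  apply(LP, 2, which.max)
}

#' Absolute decoding error
#'
#' Mean absolute distance in cm between decoded and true bins, circular
#' on circular tracks.
#'
#' @param decoded_bins,true_bins Integer bin vectors of equal length.
#' @param model A [fit_decoder()] model (for geometry), or supply
#'   `track_length_cm`/`bin_cm`/`circular` explicitly.
#' @param track_length_cm,bin_cm,circular Geometry overrides.
#' @return List: `mean_error_cm` and the per-frame `errors_cm`.
#' @export
decoding_error <- function(decoded_bins, true_bins, model = NULL,
                           track_length_cm = NULL, bin_cm = 4,
                           circular = TRUE) {
  stopifnot(length(decoded_bins) == length(true_bins))
  if (!is.null(model)) {
    track_length_cm <- model$track_length_mm / 10
    bin_cm <- model$bin_cm
    circular <- model$circular
  }
  d_cm <- abs(decoded_bins - true_bins) * bin_cm
  if (circular) d_cm <- pmin(d_cm, track_length_cm - d_cm)
  list(mean_error_cm = mean(d_cm), errors_cm = d_cm)
}

#' Chance-level decoding error on a circular track
#'
#' The expected absolute circular distance between two independent
#' uniform positions on a circle of circumference L is L/4; this is the
#' chance level used for belt (circular) environments — 50 cm for a 2 m
#' track.
#'
#' @param track_length_cm Track length in cm.
#' @return Chance error in cm.
#' @examples
#' chance_level_circular(200) # 50
#' @export
chance_level_circular <- function(track_length_cm) {
  stopifnot(track_length_cm > 0)
  track_length_cm / 4
}

#' Chance level by cell-label shuffling
#'
#' For non-circular (or any) environments the chance level is estimated
#' empirically: the cell labels of the testing activity are permuted,
#' the permuted population is decoded, and the distribution of mean
#' errors over shuffles is the chance distribution.  The observed
#' error's rank in that distribution gives an empirical p value
#' (permutation estimator `(1 + #{shuffle <= observed}) / (1 + n)`).
#'
#' @param model A [fit_decoder()] model.
#' @param events Cells x frames event matrix.
#' @param test_frames Frames to decode.
#' @param true_bins True bin per test frame.
#' @param n_shuffles Number of label permutations.
#' @param seed Integer seed.
#' @return List: `observed_error_cm`, `shuffle_errors_cm`, `p_value`.
#' @export
chance_by_label_shuffle <- function(model, events, test_frames, true_bins,
                                    n_shuffles = 100, seed = 1L) {
  events <- as.matrix(events)
  N <- nrow(events)
  stopifnot(N >= 2L)
  obs_bins <- decode_frames(events, test_frames, model)
  obs <- decoding_error(obs_bins, true_bins, model)$mean_error_cm
  set.seed(seed)
  sh <- vapply(seq_len(n_shuffles), function(k) {
    perm <- sample.int(N) # identity permutation allowed
    dec <- decode_frames(events[perm, , drop = FALSE], test_frames, model)
    decoding_error(dec, true_bins, model)$mean_error_cm
  }, numeric(1))
  list(
    observed_error_cm = obs,
    shuffle_errors_cm = sh,
    p_value = (1 + sum(sh <= obs)) / (1 + n_shuffles)
  )
}

#' Cross-validated decoding error
#'
#' Leave-one-trial-out: for every lap, the decoder is trained on all
#' other laps and tested on the left-out lap.  To compare populations of
#' different sizes, each repeat randomly subsamples `subsample` cells
#' without replacement (all cells when fewer are available) and the
#' whole leave-one-out cycle is rerun; the defaults (500 cells, 50
#' repeats) match the standard workflow for matching ROI counts between
#' rigs.
#'
#' @param events Cells x frames event matrix.
#' @param position_mm,lap Per-frame position and lap.
#' @param dt Frame period (s).
#' @param track_length_mm Track length (mm).
#' @param subsample Cells per repeat.
#' @param repeats Number of subsampling repeats.
#' @param bin_cm,tau,eps,circular Passed to [fit_decoder()].
#' @param seed Integer seed.
#' @return A `decoder_cv` object: tibble `by_repeat` (`repeat_id`,
#'   `mean_error_cm`), `mean_error_cm`, `sd_error_cm`,
#'   `chance_cm` (L/4 when circular, else `NA`).
#' @export
crossval_decode <- function(events, position_mm, lap, dt, track_length_mm,
                            subsample = 500L, repeats = 50L, bin_cm = 4,
                            tau = dt, eps = 1e-4, circular = TRUE, seed = 1L) {
  events <- as.matrix(events)
  laps <- sort(unique(lap))
  stopifnot(length(laps) >= 2L)
  N <- nrow(events)
  n_cells <- min(subsample, N)
  set.seed(seed)
  true_bins_all <- position_bins(position_mm, track_length_mm, bin_cm)
  per_repeat <- vapply(seq_len(repeats), function(r) {
    cells <- sample.int(N, n_cells)
    errs <- unlist(lapply(laps, function(l) {
      test <- which(lap == l)
      train <- which(lap != l)
      m <- fit_decoder(events[cells, , drop = FALSE], position_mm, train, dt,
                       track_length_mm, bin_cm = bin_cm, tau = tau, eps = eps,
                       circular = circular)
      dec <- decode_frames(events[cells, , drop = FALSE], test, m)
      decoding_error(dec, true_bins_all[test], m)$errors_cm
    }))
    mean(errs)
  }, numeric(1))
  structure(
    list(
      by_repeat = tibble(repeat_id = seq_len(repeats),
                         mean_error_cm = per_repeat),
      mean_error_cm = mean(per_repeat),
      sd_error_cm = sd(per_repeat),
      chance_cm = if (circular) chance_level_circular(track_length_mm / 10) else NA_real_,
      n_cells = n_cells, n_laps = length(laps),
      track_length_cm = track_length_mm / 10
    ),
    class = "decoder_cv"
  )
}
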