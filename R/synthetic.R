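#' Synthetic population specification
#'
#' Describes a population of simulated cells tied to a behavior trace:
#' a fraction of spatially tuned cells with circular-Gaussian rate
#' profiles and lognormal event amplitudes, the rest untuned (peak =
#' baseline).  Defaults describe a mid-sized imaging field of view: 600
#' cells, 40% tuned, 30 Hz frame rate, 0.2 Hz baseline and 2.5 Hz peak
#' event rate, 100 mm tuning SD.
#'
#' @param n_cells Number of cells.
#' @param fraction_tuned Fraction of tuned cells in `[0, 1]`.
#' @param frame_rate_hz Imaging frame rate.
#' @param baseline_rate_hz Out-of-field event rate (Hz).
#' @param peak_rate_hz In-field peak event rate (Hz); per-cell peaks are
#'   jittered +/-20% around this.
#' @param width_mm Gaussian tuning SD (mm).
#' @param amp_meanlog,amp_sdlog Lognormal event-amplitude parameters.
#' @return A `population_spec`.
#' @export
population_spec <- function(n_cells = 600L, fraction_tuned = 0.4,
                            frame_rate_hz = 30, baseline_rate_hz = 0.2,
                            peak_rate_hz = 2.5, width_mm = 100,
                            amp_meanlog = 0, amp_sdlog = 0.5) {
  stopifnot(fraction_tuned >= 0, fraction_tuned <= 1, n_cells >= 1,
            frame_rate_hz > 0, baseline_rate_hz >= 0, peak_rate_hz >= 0,
            width_mm > 0)
  structure(
    list(n_cells = as.integer(n_cells), fraction_tuned = fraction_tuned,
         frame_rate_hz = frame_rate_hz, baseline_rate_hz = baseline_rate_hz,
         peak_rate_hz = peak_rate_hz, width_mm = width_mm,
         amp_meanlog = amp_meanlog, amp_sdlog = amp_sdlog),
    class = "population_spec"
  )
}

#' Resample simulated behavior onto the imaging frame clock
#'
#' @param sim A [simulate_mouse()] result.
#' @param frame_rate_hz Imaging frame rate.
#' @return A tibble `t_ms`, `position_mm`, `lap` with one row per frame.
#' @export
frames_from_sim <- function(sim, frame_rate_hz = 30) {
  frame_ms <- 1000 / frame_rate_hz
  t_frames <- seq(frame_ms, max(sim$truth$t_ms), by = frame_ms)
  idx <- findInterval(t_frames, sim$truth$t_ms)
  idx[idx < 1L] <- 1L
  tibble(
    t_ms = t_frames,
    position_mm = sim$truth$position_mm[idx],
    lap = sim$truth$lap[idx]
  )
}

# analytic rate profile of one cell (Hz) at given positions
cell_rate_profile <- function(position_mm, center_mm, width_mm,
                              peak_rate_hz, baseline_rate_hz,
                              track_length_mm, circular = TRUE) {
  d <- if (circular) {
    circular_distance(position_mm, center_mm, track_length_mm)
  } else {
    abs(position_mm - center_mm)
  }
  baseline_rate_hz + (peak_rate_hz - baseline_rate_hz) *
    exp(-d^2 / (2 * width_mm^2))
}

#' Generate a synthetic place-cell population
#'
#' For each frame and cell, event occurrence is Bernoulli with
#' probability `rate(position) * dt` (erroring if that product can
#' exceed 1), where tuned cells have a circular-Gaussian rate profile
#' and untuned cells sit at baseline everywhere.  Event amplitudes are
#' lognormal.  The ground-truth labels (tuned flag, centre, width, peak)
#' travel with the session.
#'
#' @param spec A [population_spec()].
#' @param frames A behavior frame table (see [frames_from_sim()]).
#' @param track_length_mm Track length (mm).
#' @param circular Is the track circular?
#' @param seed Integer seed; cell parameters and event draws use
#'   independent substreams.
#' @return A `neural_session`: `events` (cells x frames amplitude
#'   matrix), `position_mm`, `lap`, `t_ms`, `dt`, `track_length_mm`,
#'   `circular`, and `labels` (tibble of ground truth per cell).
#' @export
generate_population <- function(spec, frames, track_length_mm,
                                circular = TRUE, seed = 1L) {
  stopifnot(inherits(spec, "population_spec"))
  if (length(unique(frames$lap)) < 2L) {
    abort("behavior must cover at least 2 laps.",
          class = "trackloop_synth_error")
  }
  dt <- 1 / spec$frame_rate_hz
  max_rate <- max(spec$peak_rate_hz * 1.2, spec$baseline_rate_hz)
  if (max_rate * dt > 1) {
    abort("frame period x max rate exceeds 1; Bernoulli thinning invalid.",
          class = "trackloop_synth_error")
  }
  N <- spec$n_cells
  Tn <- nrow(frames)

  set.seed(substream_seed(seed, 11L))
  n_tuned <- round(spec$fraction_tuned * N)
  tuned <- c(rep(TRUE, n_tuned), rep(FALSE, N - n_tuned))
  centers <- runif(N, 0, track_length_mm)
  peaks <- spec$peak_rate_hz * runif(N, 0.8, 1.2)
  peaks[!tuned] <- spec$baseline_rate_hz
  labels <- tibble(
    cell = seq_len(N), tuned = tuned, center_mm = centers,
    width_mm = spec$width_mm, peak_rate_hz = peaks,
    baseline_rate_hz = spec$baseline_rate_hz
  )
  labels$center_mm[!tuned] <- NA_real_

  set.seed(substream_seed(seed, 12L))
  events <- matrix(0, N, Tn)
  for (i in seq_len(N)) {
    rate <- if (tuned[i]) {
      cell_rate_profile(frames$position_mm, centers[i], spec$width_mm,
                        peaks[i], spec$baseline_rate_hz, track_length_mm,
                        circular)
    } else {
      rep(spec$baseline_rate_hz, Tn)
    }
    occur <- runif(Tn) < rate * dt
    n_ev <- sum(occur)
    if (n_ev > 0) {
      events[i, occur] <- rlnorm(n_ev, spec$amp_meanlog, spec$amp_sdlog)
    }
  }

  structure(
    list(events = events, position_mm = frames$position_mm,
         lap = frames$lap, t_ms = frames$t_ms, dt = dt,
         track_length_mm = track_length_mm, circular = circular,
         labels = labels, spec = spec, seed = seed),
    class = "neural_session"
  )
}

#' @export
print.neural_session <- function(x, ...) {
  cat("<neural_session> ", nrow(x$events), " cells x ", ncol(x$events),
      " frames, ", length(unique(x$lap)), " laps, track ",
      x$track_length_mm / 10, " cm\n", sep = "")
  invisible(x)
}

#' Classify place cells in a session
#'
#' Runs the full detection pipeline for every cell: tuning curve,
#' 1000-shuffle per-bin threshold, field detection with the width and
#' trial-reliability rules, then sensitivity, specificity and spatial
#' information for the cells with fields.
#'
#' @param session A `neural_session` (from [generate_population()] or
#'   [read_session_bundle()]).
#' @param n_shuffles,percentile Shuffle-test parameters.
#' @param bin_cm,smooth_sd_bins Tuning-curve parameters.
#' @param min_bins,max_bins,min_lap_frac Field criteria.
#' @param seed Integer seed (each cell uses an offset substream).
#' @return A `place_cell_scan` tibble, one row per cell: `cell`,
#'   `is_place_cell`, `n_fields`, `peak_bin`, `sensitivity`,
#'   `specificity`, `spatial_info`, `fields` (list column).
#' @export
classify_place_cells <- function(session, n_shuffles = 1000, percentile = 99,
                                 bin_cm = 4, smooth_sd_bins = 2,
                                 min_bins = 3L, max_bins = 25L,
                                 min_lap_frac = 0.5, seed = 1L) {
  N <- nrow(session$events)
  rows <- vector("list", N)
  for (i in seq_len(N)) {
    ev <- session$events[i, ]
    curve <- compute_tuning(ev, session$position_mm, session$dt,
                            session$track_length_mm, bin_cm = bin_cm,
                            smooth_sd_bins = smooth_sd_bins,
                            circular = session$circular)
    thr <- shuffle_threshold(ev, session$position_mm, session$lap,
                             session$dt, session$track_length_mm,
                             n_shuffles = n_shuffles, percentile = percentile,
                             bin_cm = bin_cm, smooth_sd_bins = smooth_sd_bins,
                             circular = session$circular,
                             seed = substream_seed(seed, i))
    ebl <- lap_bin_events(ev, session$position_mm, session$lap,
                          session$track_length_mm, bin_cm)
    fields <- detect_place_fields(curve, thr, ebl, min_bins = min_bins,
                                  max_bins = max_bins,
                                  min_lap_frac = min_lap_frac,
                                  circular = session$circular)
    has <- nrow(fields) > 0
    rows[[i]] <- tibble(
      cell = i,
      is_place_cell = has,
      n_fields = nrow(fields),
      peak_bin = if (has) fields$peak_bin[which.max(fields$peak_rate)] else NA_integer_,
      sensitivity = if (has) field_sensitivity(fields, ebl) else NA_real_,
      specificity = if (has) field_specificity(fields, ebl) else NA_real_,
      spatial_info = spatial_information(curve$rate_smooth, curve$p),
      fields = list(fields)
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("place_cell_scan", class(out))
  attr(out, "n_shuffles") <- n_shuffles
  attr(out, "bin_cm") <- bin_cm
  attr(out, "track_length_mm") <- session$track_length_mm
  out
}

#' Population tuning matrix of a session
#'
#' Smoothed tuning curves of every cell stacked into a cells x bins
#' matrix — the input for population-vector analyses.
#'
#' @param session A `neural_session`.
#' @inheritParams classify_place_cells
#' @return A cells x bins numeric matrix.
#' @export
population_tuning <- function(session, bin_cm = 4, smooth_sd_bins = 2) {
  t(vapply(seq_len(nrow(session$events)), function(i) {
    compute_tuning(session$events[i, ], session$position_mm, session$dt,
                   session$track_length_mm, bin_cm = bin_cm,
                   smooth_sd_bins = smooth_sd_bins,
                   circular = session$circular)$rate_smooth
  }, numeric(max(1L, round(session$track_length_mm / (bin_cm * 10))))))
}

#' Build the benchmark fixture families
#'
#' Generates, from one seed, the synthetic datasets the validation
#' analyses run on: a shared behavior trace (about 30 laps on a 2 m
#' circular belt), a tuned-rich population, a fully untuned null
#' population (shuffle calibration), a two-context remapping pair (the
#' second context redraws tuned-cell centres), and a rotated pair with a
#' known circular shift.
#'
#' @param seed Integer master seed.
#' @param n_cells Cells per population.
#' @param duration_ms Behavior duration (default gives ~30 laps).
#' @param track_length_mm,scale_mm_per_tick Track geometry.
#' @param fraction_tuned Tuned fraction of the tuned-rich population.
#' @param shift_bins Rotation of the rotated pair, in 4 cm bins.
#' @return A list: `behavior` (frames tibble), `sim`, `tuned_rich`,
#'   `null`, `remap_a`, `remap_b`, `rotated_a`, `rotated_b`,
#'   `shift_bins`.
#' @export
make_benchmark_suite <- function(seed = 1L, n_cells = 200L,
                                 duration_ms = 360000,
                                 track_length_mm = 2000,
                                 scale_mm_per_tick = 0.5,
                                 fraction_tuned = 0.5,
                                 shift_bins = 7L) {
  cfg <- track_config(track_length_mm, scale_mm_per_tick, circular = TRUE)
  sim <- simulate_mouse(mouse_model(), cfg, duration_ms,
                        seed = substream_seed(seed, 21L))
  frames <- frames_from_sim(sim, frame_rate_hz = 30)

  spec_rich <- population_spec(n_cells = n_cells,
                               fraction_tuned = fraction_tuned)
  spec_null <- population_spec(n_cells = n_cells, fraction_tuned = 0)

  tuned_rich <- generate_population(spec_rich, frames, track_length_mm,
                                    seed = substream_seed(seed, 22L))
  null_pop <- generate_population(spec_null, frames, track_length_mm,
                                  seed = substream_seed(seed, 23L))

  # remapping pair: same cells, independent centres in the second context
  remap_a <- generate_population(spec_rich, frames, track_length_mm,
                                 seed = substream_seed(seed, 24L))
  remap_b <- generate_population(spec_rich, frames, track_length_mm,
                                 seed = substream_seed(seed, 25L))

  # rotated pair: second context = first with all centres shifted by a
  # fixed number of bins (same event-draw substream, new centres)
  bin_mm <- 40
  rot_a <- generate_population(spec_rich, frames, track_length_mm,
                               seed = substream_seed(seed, 26L))
  rot_b <- rot_a
  shift_mm <- shift_bins * bin_mm
  rot_b$labels$center_mm <- (rot_a$labels$center_mm + shift_mm) %% track_length_mm
  set.seed(substream_seed(seed, 27L))
  dtf <- rot_b$dt
  for (i in seq_len(n_cells)) {
    lb <- rot_b$labels[i, ]
    rate <- if (isTRUE(lb$tuned)) {
      cell_rate_profile(frames$position_mm, lb$center_mm, lb$width_mm,
                        lb$peak_rate_hz, lb$baseline_rate_hz,
                        track_length_mm, TRUE)
    } else {
      rep(lb$baseline_rate_hz, nrow(frames))
    }
    occur <- runif(nrow(frames)) < rate * dtf
    row <- numeric(nrow(frames))
    if (any(occur)) {
      row[occur] <- rlnorm(sum(occur), rot_b$spec$amp_meanlog,
                           rot_b$spec$amp_sdlog)
    }
    rot_b$events[i, ] <- row
  }

  list(behavior = frames, sim = sim, tuned_rich = tuned_rich,
       null = null_pop, remap_a = remap_a, remap_b = remap_b,
       rotated_a = rot_a, rotated_b = rot_b, shift_bins = shift_bins,
       track_length_mm = track_length_mm)
}
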