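test_that("population generation is seeded and validates its inputs", {
  suite <- local_suite()
  frames <- suite$behavior
  spec <- population_spec(n_cells = 10)
  a <- generate_population(spec, frames, 2000, seed = 3)
  b <- generate_population(spec, frames, 2000, seed = 3)
  expect_identical(a$events, b$events)
  expect_identical(a$labels, b$labels)
  c2 <- generate_population(spec, frames, 2000, seed = 4)
  expect_false(identical(a$events, c2$events))

  # Bernoulli validity guard
  fast <- population_spec(n_cells = 2, frame_rate_hz = 2, peak_rate_hz = 3)
  expect_error(generate_population(fast, frames, 2000),
               class = "trackloop_synth_error")
  one_lap <- frames[frames$lap == 0, ]
  expect_error(generate_population(spec, one_lap, 2000),
               class = "trackloop_synth_error")
})

test_that("untuned cells are flat and tuned cells match their analytic profile", {
  suite <- local_suite()
  frames <- suite$behavior

  flat_spec <- population_spec(n_cells = 6, fraction_tuned = 0,
                               baseline_rate_hz = 1)
  flat <- generate_population(flat_spec, frames, 2000, seed = 5)
  for (i in 1:6) {
    tc <- compute_tuning(flat$events[i, ], flat$position_mm, flat$dt, 2000,
                         smooth_sd_bins = 0)
    # per-bin rate within binomial sampling error of the constant rate
    n_per_bin <- pmax(tc$dwell_s / flat$dt, 1)
    p <- 1 * flat$dt
    se_hz <- sqrt(p * (1 - p) / n_per_bin) / flat$dt
    expect_true(all(abs(tc$rate - 1) < 5 * se_hz))
  }

  tuned_spec <- population_spec(n_cells = 1, fraction_tuned = 1)
  tuned <- generate_population(tuned_spec, frames, 2000, seed = 6)
  lb <- tuned$labels[1, ]
  tc <- compute_tuning(tuned$events[1, ], tuned$position_mm, tuned$dt, 2000,
                       smooth_sd_bins = 0)
  analytic <- trackloop:::cell_rate_profile(tc$center_mm, lb$center_mm,
                                            lb$width_mm, lb$peak_rate_hz,
                                            lb$baseline_rate_hz, 2000)
  n_per_bin <- pmax(tc$dwell_s / tuned$dt, 1)
  # empirical rate tracks the analytic profile (4 SE + small-n slack)
  p_bin <- analytic * tuned$dt
  se_hz <- sqrt(p_bin * (1 - p_bin) / n_per_bin) / tuned$dt
  expect_true(all(abs(tc$rate - analytic) < 4 * se_hz + 0.5))
  # expected total event count within 3 SD
  exp_events <- sum(trackloop:::cell_rate_profile(
    tuned$position_mm, lb$center_mm, lb$width_mm, lb$peak_rate_hz,
    lb$baseline_rate_hz, 2000) * tuned$dt)
  n_events <- sum(tuned$events[1, ] > 0)
  expect_lt(abs(n_events - exp_events), 3 * sqrt(exp_events))
})

test_that("the generated occupancy is exactly the behavior trace occupancy", {
  suite <- local_suite()
  s <- suite$tuned_rich
  occ_session <- compute_occupancy(s$position_mm, s$dt, s$track_length_mm)
  occ_behavior <- compute_occupancy(suite$behavior$position_mm, s$dt,
                                    s$track_length_mm)
  expect_identical(occ_session, occ_behavior)
})

test_that("benchmark families have their designed structure", {
  suite <- local_suite()
  expect_true(all(!suite$null$labels$tuned))
  expect_equal(sum(suite$tuned_rich$labels$tuned), 15)

  # rotated pair: optimal shift equals the constructed rotation
  popA <- population_tuning(suite$rotated_a)
  popB <- population_tuning(suite$rotated_b)
  res <- optimal_circular_shift(popA, popB)
  expect_equal(res$shift, suite$shift_bins)

  # remapping pair: tuned-cell rate-map correlations centred near 0
  popRA <- population_tuning(suite$remap_a)
  popRB <- population_tuning(suite$remap_b)
  tuned <- which(suite$remap_a$labels$tuned)
  cors <- vapply(tuned, function(i) {
    suppressWarnings(rate_map_correlation(popRA[i, ], popRB[i, ]))
  }, numeric(1))
  expect_lt(abs(mean(cors, na.rm = TRUE)), 0.25)
})

test_that("session bundles round-trip through the plain-text format", {
  suite <- local_suite()
  spec <- population_spec(n_cells = 4)
  s <- generate_population(spec, suite$behavior[1:1500, ], 2000, seed = 9)
  dir <- withr::local_tempdir()
  write_session_bundle(s, dir)
  expect_true(all(file.exists(file.path(dir,
    c("frames.csv", "events.csv", "labels.csv", "meta.json")))))
  s2 <- read_session_bundle(dir)
  expect_equal(unname(s2$events), unname(s$events), tolerance = 1e-12)
  expect_equal(s2$position_mm, s$position_mm)
  expect_equal(s2$dt, s$dt)
  expect_equal(s2$track_length_mm, 2000)
})
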