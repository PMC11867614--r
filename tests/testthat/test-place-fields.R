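# build a curve/threshold/lap-event triple with a supra-threshold run of
# given width, events present on a controllable fraction of laps
run_fixture <- function(width, B = 50, n_laps = 10, lap_frac = 1) {
  rate <- rep(0.1, B)
  bins <- if (width > 0) seq_len(width) + 10 else integer()
  rate[bins] <- 2
  thr <- rep(1, B)
  M <- matrix(0L, n_laps, B)
  active_laps <- seq_len(round(lap_frac * n_laps))
  if (length(bins)) M[active_laps, bins[1]] <- 1L
  list(rate = rate, thr = thr, M = M)
}

test_that("field width rules: at least 3 bins (12 cm), fewer than 25 (100 cm)", {
  f2 <- run_fixture(2)
  expect_equal(nrow(detect_place_fields(f2$rate, f2$thr, f2$M)), 0)
  f3 <- run_fixture(3)
  fields <- detect_place_fields(f3$rate, f3$thr, f3$M)
  expect_equal(nrow(fields), 1)
  expect_equal(fields$width_bins, 3)
  f24 <- run_fixture(24)
  expect_equal(nrow(detect_place_fields(f24$rate, f24$thr, f24$M)), 1)
  f25 <- run_fixture(25)
  expect_equal(nrow(detect_place_fields(f25$rate, f25$thr, f25$M)), 0)
})

test_that("the 50% trial-reliability rule filters unreliable runs", {
  ok <- run_fixture(5, lap_frac = 0.5)
  expect_equal(nrow(detect_place_fields(ok$rate, ok$thr, ok$M)), 1)
  bad <- run_fixture(5, lap_frac = 0.4)
  expect_equal(nrow(detect_place_fields(bad$rate, bad$thr, bad$M)), 0)
})

test_that("runs may wrap across the track seam on circular tracks", {
  B <- 50
  rate <- rep(0.1, B); rate[c(49, 50, 1, 2)] <- 2
  thr <- rep(1, B)
  M <- matrix(1L, 10, B)
  fields <- detect_place_fields(rate, thr, M)
  expect_equal(nrow(fields), 1)
  expect_equal(fields$width_bins, 4)
  expect_equal(fields$start_bin, 49)
  expect_equal(fields$end_bin, 2)
  # non-circular: the same pattern splits into two sub-minimum runs
  expect_equal(nrow(detect_place_fields(rate, thr, M, circular = FALSE)), 0)
})

test_that("sensitivity is the fraction of laps with an in-field event", {
  f <- run_fixture(5, lap_frac = 1)
  fields <- detect_place_fields(f$rate, f$thr, f$M)
  expect_equal(field_sensitivity(fields, f$M), 1)
  f5 <- run_fixture(5, lap_frac = 0.5)
  fields5 <- detect_place_fields(f5$rate, f5$thr, f5$M)
  expect_equal(field_sensitivity(fields5, f5$M), 0.5)

  # binomial property: Bernoulli(q) in-field events over many laps
  set.seed(31)
  q <- 0.7; n_laps <- 400
  M <- matrix(0L, n_laps, 50)
  M[, 12] <- rbinom(n_laps, 1, q)
  fields_b <- tibble::tibble(start_bin = 11L, end_bin = 15L, width_bins = 5L,
                             peak_bin = 12L, peak_rate = 2, lap_fraction = q)
  expect_lt(abs(field_sensitivity(fields_b, M) - q), 3 * sqrt(q * (1 - q) / n_laps))
})

test_that("specificity averages per-lap in-field event fractions", {
  M <- matrix(0L, 3, 50)
  fields <- tibble::tibble(start_bin = 11L, end_bin = 15L, width_bins = 5L,
                           peak_bin = 12L, peak_rate = 2, lap_fraction = 1)
  # lap ratios {1, 0.5, 0} -> 0.5
  M[1, 12] <- 2L
  M[2, 12] <- 1L; M[2, 30] <- 1L
  M[3, 30] <- 1L
  expect_equal(field_specificity(fields, M), 0.5)
  # every lap one in + one out -> 0.5
  M2 <- matrix(0L, 10, 50); M2[, 12] <- 1L; M2[, 40] <- 1L
  expect_equal(field_specificity(fields, M2), 0.5)
  # all in-field -> 1; no events -> NA with warning
  M3 <- matrix(0L, 10, 50); M3[, 13] <- 1L
  expect_equal(field_specificity(fields, M3), 1)
  expect_warning(v <- field_specificity(fields, matrix(0L, 5, 50)),
                 "specificity undefined")
  expect_true(is.na(v))
})

test_that("multi-field cells average their per-field metrics", {
  M <- matrix(0L, 4, 50)
  M[1:4, 5] <- 1L          # field A: events every lap
  M[1:2, 30] <- 1L         # field B: events on half the laps
  fields <- tibble::tibble(start_bin = c(4L, 29L), end_bin = c(6L, 31L),
                           width_bins = c(3L, 3L), peak_bin = c(5L, 30L),
                           peak_rate = c(2, 2), lap_fraction = c(1, 0.5))
  expect_equal(field_sensitivity(fields, M), (1 + 0.5) / 2)
})

test_that("the two-proportion z-test reproduces the reference value", {
  r0 <- two_proportion_ztest(30, 100, 30, 100)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  r <- two_proportion_ztest(3253, 9195, 6101, 13454)
  expect_equal(round(r$statistic, 2), 14.96)
  expect_lt(r$p_value, 1e-49)

  # independent oracle: z^2 equals the chi-square of prop.test without
  # continuity correction
  set.seed(32)
  for (i in 1:20) {
    n1 <- sample(50:500, 1); n2 <- sample(50:500, 1)
    k1 <- rbinom(1, n1, 0.4); k2 <- rbinom(1, n2, 0.5)
    if (k1 == 0 || k2 == 0) next
    z <- two_proportion_ztest(k1, n1, k2, n2)$statistic
    chi <- suppressWarnings(
      stats::prop.test(c(k1, k2), c(n1, n2), correct = FALSE)$statistic)
    expect_equal(z^2, unname(chi), tolerance = 1e-10)
  }
})

test_that("shuffle thresholds are seeded and extreme tuning always exceeds them", {
  s <- local_suite()
  # a perfectly tuned cell: events only when the animal is near 600 mm
  pos <- s$behavior$position_mm
  lap <- s$behavior$lap
  ev <- as.numeric(circular_distance(pos, 600, 2000) < 40)
  th1 <- shuffle_threshold(ev, pos, lap, 1 / 30, 2000, n_shuffles = 200,
                           seed = 5)
  th2 <- shuffle_threshold(ev, pos, lap, 1 / 30, 2000, n_shuffles = 200,
                           seed = 5)
  expect_identical(th1, th2)
  tc <- compute_tuning(ev, pos, 1 / 30, 2000)
  peak_bin <- which.max(tc$rate_smooth)
  expect_gt(tc$rate_smooth[peak_bin], th1$threshold[peak_bin])
  expect_error(shuffle_threshold(ev, pos, rep(0L, length(pos)), 1 / 30, 2000),
               class = "trackloop_analysis_error")
})
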