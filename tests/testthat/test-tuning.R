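test_that("event binarization thresholds at median + 4 MAD of the raw trace", {
  expect_equal(binarize_events(numeric(10), rnorm(10)), numeric(10))

  # raw trace engineered so median + 4*MAD = 5
  raw <- c(0, 1.25, -1.25, 1.25, -1.25)
  expect_equal(median(raw) + 4 * mad(raw, constant = 1), 5)
  expect_equal(binarize_events(c(0, 1, 10, 4.9, 5.1), raw),
               c(0, 0, 10, 0, 5.1))

  # synthetic train with known above/below counts
  set.seed(21)
  raw2 <- rnorm(5000)
  thr <- median(raw2) + 4 * mad(raw2, constant = 1)
  amps <- runif(5000, 0, 2 * thr)
  out <- binarize_events(amps, raw2)
  expect_equal(sum(out > 0), sum(amps > thr))

  expect_warning(binarize_events(c(0, 2), c(1, 1)), "zero MAD")
})

test_that("significant-transient selection matches the normal tail", {
  set.seed(22)
  x <- rnorm(1e5)
  frac <- mean(select_significant_transients(x))
  expect_lt(abs(frac - pnorm(3, lower.tail = FALSE)), 5e-4)
  expect_equal(sum(select_significant_transients(rep(1, 100))), 0)
  y <- rnorm(1000); y[500] <- 10 * sd(y)
  expect_equal(which(select_significant_transients(y)), 500L)
})

test_that("tuning curves conserve counts and smoothing fixes constants", {
  # uniform events over uniform occupancy -> flat, smoothing-invariant
  pos <- rep(seq(20, 1980, by = 40), times = 20)
  ev <- rep(1, length(pos))
  tc <- compute_tuning(ev, pos, 0.1, 2000)
  expect_equal(diff(range(tc$rate_smooth)), 0)
  expect_equal(tc$rate_smooth, tc$rate)

  # count conservation pre-smoothing
  set.seed(23)
  pos2 <- runif(3000, 0, 2000)
  ev2 <- rbinom(3000, 1, 0.1) * runif(3000, 0.5, 2)
  tc2 <- compute_tuning(ev2, pos2, 1 / 30, 2000)
  expect_equal(sum(tc2$rate * tc2$dwell_s), sum(ev2 > 0))

  # a single event in bin 1 smears symmetrically across the seam
  pos3 <- rep(seq(20, 1980, by = 40), times = 5)
  ev3 <- numeric(length(pos3)); ev3[pos3 == 20][1] <- 1
  tc3 <- compute_tuning(ev3, pos3, 0.1, 2000)
  expect_equal(tc3$rate_smooth[2], tc3$rate_smooth[50])
  expect_equal(tc3$rate_smooth[3], tc3$rate_smooth[49])
  expect_equal(which.max(tc3$rate_smooth), 1L)
})

test_that("spatial information has its closed-form limits", {
  B <- 50
  p <- rep(1 / B, B)
  expect_equal(spatial_information(rep(2, B), p), 0)
  one_bin <- c(10, rep(0, B - 1))
  expect_equal(spatial_information(one_bin, p), log2(B))
  # independent direct-sum oracle on a random curve
  set.seed(24)
  rate <- runif(B)
  pr <- runif(B); pr <- pr / sum(pr)
  lbar <- sum(pr * rate)
  direct <- 0
  for (i in 1:B) {
    if (rate[i] > 0) direct <- direct + pr[i] * (rate[i] / lbar) *
        log2(rate[i] / lbar)
  }
  expect_equal(spatial_information(rate, pr), direct, tolerance = 1e-12)
  expect_gte(spatial_information(rate, pr), 0)
})

test_that("rate-map correlation matches the textbook formula", {
  a <- c(1, 2, 3, 4)
  expect_equal(rate_map_correlation(a, a), 1)
  expect_equal(rate_map_correlation(a, mean(a) - (a - mean(a))), -1)
  set.seed(25)
  x <- runif(50); y <- runif(50)
  direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(rate_map_correlation(x, y), direct, tolerance = 1e-12)
  expect_warning(r <- rate_map_correlation(rep(1, 4), a), "zero-variance")
  expect_true(is.na(r))
})

test_that("the optimal circular shift recovers a constructed rotation", {
  set.seed(26)
  pop <- matrix(runif(30 * 50), 30, 50)
  rot <- trackloop:::rotate_population(pop, 7)
  res <- optimal_circular_shift(pop, rot)
  expect_equal(res$shift, 7L)
  res0 <- optimal_circular_shift(pop, pop)
  expect_equal(res0$shift, 0L)
  expect_equal(res0$mean_correlation, 1)
  # noisy rotation still recovered; exhaustive-search table is returned
  noisy <- rot + matrix(rnorm(30 * 50, 0, 0.1), 30, 50)
  resn <- optimal_circular_shift(pop, noisy)
  expect_equal(resn$shift, 7L)
  expect_equal(nrow(resn$by_shift), 50)
  expect_equal(resn$by_shift$shift[which.max(resn$by_shift$mean_correlation)],
               7L)
})

test_that("occupancy normalizes to a probability over 4 cm bins", {
  set.seed(27)
  pos <- runif(2000, 0, 2000)
  occ <- compute_occupancy(pos, 1 / 30, 2000)
  expect_equal(nrow(occ), 50)
  expect_equal(sum(occ$p), 1)
  expect_equal(sum(occ$dwell_s), 2000 / 30)
  expect_error(compute_occupancy(numeric(0), 1 / 30, 2000),
               class = "trackloop_analysis_error")
})
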