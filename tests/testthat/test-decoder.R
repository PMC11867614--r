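test_that("the posterior matches the brute-force product formula and sums to 1", {
  set.seed(41)
  N <- 4; B <- 5
  f <- matrix(runif(N * B, 0.01, 0.5), N, B)
  model <- structure(
    list(f = f, tau = 0.2, bin_centers_mm = (1:B - 0.5) * 40,
         track_length_mm = B * 40, bin_cm = 4, circular = TRUE,
         empty_bins = integer(), dt = 0.2),
    class = "decoder_model")
  for (rep in 1:10) {
    a <- rbinom(N, 3, 0.4)
    p <- decode_posterior(a, model)
    expect_equal(sum(p), 1, tolerance = 1e-10)
    # independent direct evaluation of C * prod(f^a) * exp(-tau * sum(f))
    unnorm <- vapply(1:B, function(b) {
      prod(f[, b]^a) * exp(-0.2 * sum(f[, b]))
    }, numeric(1))
    expect_equal(as.numeric(p), unnorm / sum(unnorm), tolerance = 1e-10)
    expect_equal(attr(p, "decoded_bin"), unname(which.max(unnorm)))
  }
})

test_that("degenerate posteriors behave: uniform rates and single-bin cells", {
  N <- 3; B <- 6
  uni <- structure(
    list(f = matrix(0.2, N, B), tau = 0.1,
         bin_centers_mm = (1:B - 0.5) * 40, track_length_mm = B * 40,
         bin_cm = 4, circular = TRUE, empty_bins = integer(), dt = 0.1),
    class = "decoder_model")
  p <- decode_posterior(rep(0, N), uni)
  expect_equal(as.numeric(p), rep(1 / B, B), tolerance = 1e-12)
  expect_equal(attr(p, "decoded_bin"), 1L) # tie -> lowest index

  f <- matrix(1e-4, N, B); f[1, 3] <- 0.9
  single <- uni; single$f <- f
  p2 <- decode_posterior(c(1, 0, 0), single)
  expect_equal(attr(p2, "decoded_bin"), 3L)
})

test_that("fitted rates are per-bin means of binarized training activity", {
  # one cell active only in bin 3
  pos <- rep(seq(20, 1980, by = 40), times = 4) # 4 passes over 50 bins
  Tn <- length(pos)
  ev <- matrix(0, 2, Tn)
  ev[1, which(trackloop:::position_bins(pos, 2000) == 3L)[1:2]] <- 1.5
  m <- fit_decoder(ev, pos, seq_len(Tn), 1 / 30, 2000)
  expect_equal(m$f_raw[1, 3], 2 / 4) # 2 active frames of 4 visits
  expect_true(all(m$f_raw[1, -3] == 0))
  expect_true(all(m$f >= 1e-4)) # floor keeps the log finite
  expect_equal(m$f[1, 3], 0.5)
})

test_that("decoding error uses circular distance and L/4 is the chance level", {
  expect_equal(chance_level_circular(200), 50)
  expect_equal(chance_level_circular(400), 100)

  err <- decoding_error(c(1, 10), c(1, 10), track_length_cm = 200)
  expect_equal(err$mean_error_cm, 0)
  # antipodal error on a 200 cm circle is 100 cm
  err2 <- decoding_error(c(26), c(1), track_length_cm = 200)
  expect_equal(err2$mean_error_cm, 100)

  # Monte-Carlo oracle for the closed form
  set.seed(42)
  n <- 2e5
  d <- circular_distance(runif(n, 0, 200), runif(n, 0, 200), 200)
  se <- sd(d) / sqrt(n)
  expect_lt(abs(mean(d) - 50), 3 * se)
})

test_that("cross-validated decoding is deterministic given a seed and exact on
           deterministic repeating laps", {
  # two identical laps of a deterministic population: one cell per bin,
  # active exactly when the animal is in its bin
  B <- 20; L <- B * 40
  pos <- rep(seq(20, by = 40, length.out = B), times = 2)
  lap <- rep(0:1, each = B)
  ev <- matrix(0, B, length(pos))
  for (i in 1:B) ev[i, trackloop:::position_bins(pos, L) == i] <- 1
  cv <- crossval_decode(ev, pos, lap, 0.1, L, subsample = B, repeats = 2,
                        seed = 1)
  expect_equal(cv$mean_error_cm, 0)
  expect_equal(cv$chance_cm, B * 4 / 4)

  s <- local_suite()$tuned_rich
  cv1 <- crossval_decode(s$events, s$position_mm, s$lap, s$dt,
                         s$track_length_mm, subsample = 20, repeats = 3,
                         seed = 7)
  cv2 <- crossval_decode(s$events, s$position_mm, s$lap, s$dt,
                         s$track_length_mm, subsample = 20, repeats = 3,
                         seed = 7)
  expect_identical(cv1$by_repeat, cv2$by_repeat)
  expect_s3_class(tidy(cv1), "tbl_df")
  expect_equal(nrow(tidy(cv1)), 3)
  expect_equal(glance(cv1)$n_cells, 20)
})

test_that("label shuffling detaches tuning: tuned populations beat their shuffles", {
  s <- local_suite()$tuned_rich
  train <- which(s$lap < max(s$lap) - 3)
  test <- which(s$lap >= max(s$lap) - 3)
  m <- fit_decoder(s$events, s$position_mm, train, s$dt, s$track_length_mm)
  tb <- trackloop:::position_bins(s$position_mm, s$track_length_mm)[test]
  ch <- chance_by_label_shuffle(m, s$events, test, tb, n_shuffles = 30,
                                seed = 3)
  expect_lt(ch$observed_error_cm, mean(ch$shuffle_errors_cm))
  expect_lt(ch$p_value, 0.1)
  # shuffle errors concentrate near the circular chance level
  expect_lt(abs(mean(ch$shuffle_errors_cm) - 50), 15)
})
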