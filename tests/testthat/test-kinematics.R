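test_that("whisker angle follows the two-point arctangent, protraction-positive", {
  # 45 deg: equal x and y displacement toward protraction (up in the image)
  lm45 <- tibble::tibble(
    frame = 0L, time = 0,
    bodypart = c("C3_1", "C3_2"),
    x = c(100, 200), y = c(100, 0), likelihood = 1)
  expect_equal(compute_whisker_angle(lm45)$angle, 45)

  # random geometries match a direct per-frame atan2 oracle
  set.seed(21)
  n <- 50
  x2 <- runif(n, -100, 100); y2 <- runif(n, -100, 100)
  lm <- dplyr::bind_rows(
    tibble::tibble(frame = 0:(n - 1), time = 0:(n - 1), bodypart = "C3_1",
                   x = 0, y = 0, likelihood = 1),
    tibble::tibble(frame = 0:(n - 1), time = 0:(n - 1), bodypart = "C3_2",
                   x = x2, y = y2, likelihood = 1))
  got <- compute_whisker_angle(lm)$angle
  expect_equal(got, atan2(-y2, x2) * 180 / pi)
})

test_that("bad frames are interpolated up to the gap limit", {
  n <- 30
  lm <- dplyr::bind_rows(
    tibble::tibble(frame = 0:(n - 1), time = (0:(n - 1)) / 299, bodypart = "C3_1",
                   x = 0, y = 0, likelihood = 1),
    tibble::tibble(frame = 0:(n - 1), time = (0:(n - 1)) / 299, bodypart = "C3_2",
                   x = 100, y = -(0:(n - 1)), likelihood = 1))
  lm$likelihood[lm$bodypart == "C3_2"][5:6] <- 0.1   # short gap: interpolated
  expect_message(ang <- compute_whisker_angle(lm, max_gap = 3), "interpolating")
  expect_false(any(is.na(ang$angle)))
  lm$likelihood[lm$bodypart == "C3_2"][10:20] <- 0.1 # long gap: stays NA
  suppressMessages(ang2 <- compute_whisker_angle(lm, max_gap = 3))
  expect_true(any(is.na(ang2$angle)))
})

test_that("Hilbert decomposition recovers sinusoid amplitude, set point and phase slope", {
  tr <- fix_sine_trace(A = 12, B = 30, f = 8)
  kin <- decompose_whisking(tr)
  mid <- kin$time > 2 & kin$time < 28
  expect_equal(mean(kin$amplitude[mid]), 12, tolerance = 0.02)
  expect_equal(mean(kin$setpoint[mid]), 30, tolerance = 0.02)
  expect_true(all(kin$amplitude >= 0))
  # unwrapped phase slope = 2 pi f
  ph <- kin$phase[mid]
  dph <- diff(ph); dph[dph < -pi] <- dph[dph < -pi] + 2 * pi
  slope <- mean(dph) * 299
  expect_equal(slope, 2 * pi * 8, tolerance = 0.01)
  # constant trace: amplitude ~ 0 (away from zero-phase filter edge
  # transients)
  flat <- tibble::tibble(time = tr$time, angle = 25)
  kflat <- decompose_whisking(flat)
  expect_lt(max(kflat$amplitude[kflat$time > 2 & kflat$time < 28]), 1e-6)
  # band outside Nyquist rejected
  expect_error(decompose_whisking(tr, band = c(4, 200)), "Nyquist")
})

test_that("bout detection applies the 10 degree threshold with merge/drop rules", {
  t <- seq(0, 60, by = 1 / 299)
  always <- tibble::tibble(time = t, amplitude = 15)
  b1 <- detect_whisking_bouts(always, amp_lowpass = 0)
  expect_equal(nrow(b1), 1)
  expect_equal(b1$onset, 0)
  expect_equal(b1$offset, 60, tolerance = 0.01)

  never <- tibble::tibble(time = t, amplitude = 5)
  expect_equal(nrow(detect_whisking_bouts(never, amp_lowpass = 0)), 0)

  # exact on a noise-free step-amplitude trace
  step <- tibble::tibble(time = t, amplitude = ifelse(t >= 20 & t <= 30, 15, 2))
  bs <- detect_whisking_bouts(step, amp_lowpass = 0)
  expect_equal(nrow(bs), 1)
  expect_equal(bs$onset, 20, tolerance = 1 / 299)
  expect_equal(bs$offset, 30, tolerance = 1 / 299)

  # gaps below min_gap merge; bouts below min_bout drop
  amp <- rep(2, length(t))
  amp[t >= 10 & t <= 12] <- 15
  amp[t >= 12.1 & t <= 14] <- 15      # 0.1 s gap -> merged
  amp[t >= 20 & t <= 20.2] <- 15      # 0.2 s bout -> dropped
  bm <- detect_whisking_bouts(tibble::tibble(time = t, amplitude = amp),
                              amp_lowpass = 0)
  expect_equal(nrow(bm), 1)
  expect_equal(bm$onset, 10, tolerance = 1 / 299)
  expect_equal(bm$offset, 14, tolerance = 1 / 299)
})

test_that("bout mask and table are equivalent and merging is idempotent", {
  bouts <- tibble::tibble(onset = c(1, 5, 9), offset = c(2, 6.5, 9.5))
  t <- seq(0, 12, by = 0.01)
  mask <- bouts_to_mask(bouts, t)
  back <- mask_to_bouts(mask, t)
  expect_equal(nrow(back), 3)
  expect_equal(back$onset, bouts$onset, tolerance = 0.011)
  expect_equal(back$offset, bouts$offset, tolerance = 0.011)
  m1 <- whiskpop:::merge_and_filter_bouts(bouts, min_bout = 0.5, min_gap = 0.25)
  m2 <- whiskpop:::merge_and_filter_bouts(m1, min_bout = 0.5, min_gap = 0.25)
  expect_identical(m1, m2)
})

test_that("detected bout onsets track generator ground truth", {
  errs <- unlist(lapply(1:3, function(s) {
    sim <- simulate_whisking(whisk_sim_params(duration = 120, seed = s))
    kin <- decompose_whisking(sim$trace)
    b <- detect_whisking_bouts(kin)
    vapply(sim$bouts$onset, function(on) min(abs(b$onset - on)), numeric(1))
  }))
  expect_lt(median(errs), 0.1)
})

test_that("decomposition recovers the generator's amplitude and set point", {
  sim <- simulate_whisking(whisk_sim_params(duration = 60, noise_sd = 0, seed = 31))
  kin <- decompose_whisking(sim$trace)
  # steady whisking frames away from bout edges
  steady <- sim$truth$whisking &
    !bouts_to_mask(dplyr::mutate(sim$bouts, onset = onset - 0.4,
                                 offset = onset + 0.8), sim$trace$time) &
    bouts_to_mask(dplyr::mutate(sim$bouts, onset = onset + 0.4), sim$trace$time)
  expect_gt(sum(steady), 100)
  expect_lt(median(abs(kin$amplitude[steady] - sim$truth$amplitude[steady])), 2)
  expect_lt(median(abs(kin$setpoint[steady] - sim$truth$setpoint[steady])), 2)
})

test_that("bout-aligned averaging behaves like a mean of trials", {
  t <- seq(0, 100, by = 1 / 299)
  shape <- function(u) ifelse(u > 0 & u < 1, sin(pi * u), 0)
  onsets <- seq(10, 90, by = 10)
  ang <- rowSums(vapply(onsets, function(on) 20 * shape(t - on),
                        numeric(length(t))))
  tr <- tibble::tibble(time = t, angle = ang)
  bouts <- tibble::tibble(onset = onsets, offset = onsets + 1)
  avg <- trial_average_whisking(tr, bouts)
  # identical trials: average equals any single trial, SD ~ 0
  one <- 20 * shape(avg$t)
  expect_lt(max(abs(avg$mean_angle - one)), 1e-6)
  expect_lt(max(avg$sd_angle), 1e-6)
  expect_equal(unique(avg$n), 9)
  # single usable bout: average = that trial, SD = 0
  avg1 <- trial_average_whisking(tr, bouts[3, ])
  expect_equal(unique(avg1$n), 1)
  expect_true(all(avg1$sd_angle == 0))
  # zero usable bouts: explicit empty result
  expect_warning(
    empty <- trial_average_whisking(tr, tibble::tibble(onset = 99.5, offset = 100)),
    "no bout")
  expect_equal(nrow(empty), 0)
})

test_that("standard error of the bout average shrinks as 1/sqrt(n)", {
  set.seed(77)
  t <- seq(0, 200, by = 1 / 100)
  tr <- tibble::tibble(time = t, angle = rnorm(length(t), 0, 5))
  est <- function(n_bouts) {
    onsets <- seq(5, 195, length.out = n_bouts)
    a <- trial_average_whisking(tr, tibble::tibble(onset = onsets,
                                                   offset = onsets + 1),
                                window = c(-0.5, 0.5))
    sd(a$mean_angle)
  }
  ratio <- est(40) / est(10)
  expect_gt(ratio, 0.3)
  expect_lt(ratio, 0.85)   # ~ sqrt(10/40) = 0.5
})
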