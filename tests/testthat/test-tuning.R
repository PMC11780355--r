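test_that("tuning curves have 11 bins and recover flat and concentrated tuning", {
  curves <- compute_tuning_curve(fix_pop$spikes, fix_sim$trace)
  expect_equal(max(curves$bin), 11)
  expect_equal(dplyr::n_distinct(curves$bin), 11)
  occ <- dplyr::distinct(curves, bin, occupancy)
  expect_equal(sum(occ$occupancy), 1)
  expect_true(all(curves$rate >= 0))

  # homogeneous Poisson unit: flat within 3 SE in well-occupied bins
  set.seed(3)
  dur <- 200
  t <- seq(0, dur, by = 1 / 299)
  tr <- tibble::tibble(time = t, angle = 30 + 10 * sin(2 * pi * 0.5 * t))
  sp <- tibble::tibble(unit_id = 1L, time = sort(runif(20 * dur, 0, dur)))
  cv <- compute_tuning_curve(sp, tr)
  well <- cv$n_timebins > 50
  expect_true(all(abs(cv$rate[well] - 20) <= 3.5 * cv$rate_se[well]))

  # spikes emitted only at angles in bin 6: rate nonzero only there
  edges <- seq(min(tr$angle), max(tr$angle), length.out = 12)
  in6 <- tr$angle >= edges[6] & tr$angle < edges[7]
  sp6 <- tibble::tibble(unit_id = 1L, time = tr$time[in6] + 1e-4)
  cv6 <- compute_tuning_curve(sp6, tr)
  expect_gt(cv6$rate[cv6$bin == 6], 0)
  expect_lt(sum(cv6$rate[cv6$bin != 6]) / cv6$rate[cv6$bin == 6], 0.15)

  # zero-spike unit flagged sparse with an all-zero curve
  sp0 <- dplyr::bind_rows(sp6, tibble::tibble(unit_id = 2L, time = numeric(0)))
  cv0 <- compute_tuning_curve(sp0, tr)
  u2 <- dplyr::filter(cv0, unit_id == 2)
  expect_true(all(u2$sparse))
  expect_true(all(u2$rate == 0))
})

test_that("circular-shift shuffles flatten tuned curves and are seeded", {
  # aperiodic angle trace (periodic traces would stay tuned under circular
  # shifts by construction)
  tr <- fix_sim$trace
  edges <- seq(min(tr$angle), max(tr$angle), length.out = 12)
  in_top <- tr$angle >= edges[10]
  sp <- tibble::tibble(unit_id = 1L, time = tr$time[in_top] + 1e-4)
  real <- compute_tuning_curve(sp, tr)
  real_range <- diff(range(real$rate))
  null <- shuffle_tuning_null(sp, tr, n_shuffles = 60, seed = 5)
  null_ranges <- null |>
    dplyr::group_by(shuffle) |>
    dplyr::summarise(r = diff(range(rate)))
  expect_gte(mean(null_ranges$r < real_range), 0.95)
  # seeded determinism and zero-shift exclusion
  null2 <- shuffle_tuning_null(sp, tr, n_shuffles = 60, seed = 5)
  expect_identical(null, null2)
  expect_false(isTRUE(all.equal(
    dplyr::filter(null, shuffle == 1)$rate, real$rate)))
  expect_error(shuffle_tuning_null(sp, tr, n_shuffles = 0), "n_shuffles")
})

test_that("spline smoothing projects onto a 7-function cubic basis", {
  # a cubic polynomial lies in the span: residual ~ 0
  cubic <- fix_curve(5 + 0.3 * (1:11) - 0.1 * (1:11)^2 + 0.01 * (1:11)^3)
  fit <- smooth_tuning(cubic)
  expect_equal(nrow(fit$coefficients), 7)
  expect_lt(max(abs(fit$curves$rate_smooth - cubic$rate)), 1e-8)

  # constant curve stays constant
  fitc <- smooth_tuning(fix_curve(rep(4, 11)))
  expect_lt(diff(range(fitc$curves$rate_smooth)), 1e-8)

  # noisy bump: smoothed closer (L2) to the truth than the raw curve
  set.seed(8)
  truth <- 10 * exp(-((1:11) - 6)^2 / 4)
  noisy <- truth + rnorm(11, 0, 1.5)
  fitn <- smooth_tuning(fix_curve(noisy))
  expect_lt(sum((fitn$curves$rate_smooth - truth)^2),
            sum((noisy - truth)^2))

  # under-determined unit falls back to ridge and is flagged
  sparse <- fix_curve(c(1, 2, 3, 4, 5, rep(0, 6)),
                      occupied = c(rep(TRUE, 5), rep(FALSE, 6)))
  fits <- smooth_tuning(sparse)
  expect_true(fits$flags$ridged[1])
})

test_that("k-means taxonomy recovers planted families and defaults to k = 8", {
  expect_equal(formals(cluster_tuning)$k, 8)
  set.seed(12)
  mk <- function(shape, ids) {
    purrr::map_dfr(ids, function(i) fix_curve(shape + rnorm(11, 0, 0.3),
                                              unit_id = i))
  }
  curves <- dplyr::bind_rows(
    mk(10 * exp(-((1:11) - 3)^2 / 3), 1:15),
    mk(2 + 0.8 * (1:11), 16:30))
  fits <- smooth_tuning(curves)
  cl <- cluster_tuning(fits, k = 2, seed = 4)
  truth <- rep(1:2, each = 15)
  expect_gt(mclust::adjustedRandIndex(cl$labels$cluster, truth), 0.95)
  # cluster means are reported on the raw-rate scale
  expect_true(all(c("cluster", "bin", "rate") %in% names(cl$cluster_curves)))
  # identical curves collapse to one effective cluster, logged
  same <- purrr::map_dfr(1:6, function(i) fix_curve(rep(3, 11), unit_id = i))
  expect_message(cls <- cluster_tuning(smooth_tuning(same), k = 2, seed = 1),
                 "distinct")
  expect_equal(dplyr::n_distinct(cls$labels$cluster), 1)
  expect_error(cluster_tuning(smooth_tuning(same), k = 10), "k = 10")
})

test_that("tuning entropy matches direct pmf arithmetic and its bounds", {
  uni <- tuning_entropy(fix_curve(rep(2, 11)))
  expect_equal(uni$entropy, log(11), tolerance = 1e-12)
  single <- tuning_entropy(fix_curve(c(5, rep(0, 10))))
  expect_equal(single$entropy, 0)
  mixed <- tuning_entropy(fix_curve(c(0.5, 0.25, 0.25, rep(0, 8))))
  expect_equal(mixed$entropy, -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)),
               tolerance = 1e-12)
  expect_equal(mixed$entropy, 1.0397, tolerance = 1e-4)
  expect_warning(z <- tuning_entropy(fix_curve(rep(0, 11))), "all-zero")
  expect_true(is.na(z$entropy))
  # bounds over random curves
  set.seed(2)
  for (i in 1:20) {
    h <- tuning_entropy(fix_curve(runif(11)))$entropy
    expect_gte(h, 0); expect_lte(h, log(11) + 1e-12)
  }
})

test_that("KL divergence matches the direct sum and satisfies Gibbs' inequality", {
  p <- fix_curve(c(0.5, 0.5, rep(0, 9)))
  q <- fix_curve(c(0.9, 0.1, rep(0, 9)))
  kl <- tuning_kl(p, q, eps = 1e-12)
  expect_equal(kl$kl, 0.5 * log(0.5 / 0.9) + 0.5 * log(0.5 / 0.1),
               tolerance = 1e-6)
  expect_equal(kl$kl, 0.5108, tolerance = 1e-4)
  expect_equal(tuning_kl(p, p)$kl, 0)
  # symmetrized option
  ks <- tuning_kl(p, q, eps = 1e-12, symmetrized = TRUE)
  krev <- tuning_kl(q, p, eps = 1e-12)
  expect_equal(ks$kl, (kl$kl + krev$kl) / 2)
  # non-negativity on random pairs
  set.seed(6)
  for (i in 1:15) {
    a <- fix_curve(runif(11)); b <- fix_curve(runif(11))
    expect_gte(tuning_kl(a, b)$kl, -1e-12)
  }
  expect_error(tuning_kl(p, fix_curve(runif(9))), "binning")
})

test_that("population tuning averages units and marks the resting point", {
  one <- fix_curve(1:11)
  expect_equal(population_tuning(one)$rate_mean, 1:11)
  pair <- dplyr::bind_rows(fix_curve(1:11, unit_id = 1),
                           fix_curve(11:1, unit_id = 2))
  flat <- population_tuning(pair)
  expect_true(all(flat$rate_mean == 6))
  expect_equal(sum(flat$resting), 1)
})

test_that("entropy-difference distributions separate drift from stability", {
  # post-drug flattening yields right-skewed entropy differences; no change
  # yields differences concentrated at zero
  set.seed(14)
  n_units <- 60
  pre_rates <- purrr::map(1:n_units, ~10 * exp(-((1:11) - sample(3:9, 1))^2 / 2) + 0.2)
  # most units barely drift, a few flatten strongly -> right-tailed deltas
  f <- runif(n_units)^3
  drift <- purrr::map2(pre_rates, f, ~(1 - .y) * .x + .y * mean(.x))
  h <- function(lst, ids) {
    tuning_entropy(purrr::map_dfr(seq_along(lst),
                                  function(i) fix_curve(lst[[i]], unit_id = ids[i])))$entropy
  }
  d_drift <- h(drift, 1:n_units) - h(pre_rates, 1:n_units)
  d_null <- h(pre_rates, 1:n_units) - h(pre_rates, 1:n_units)
  expect_gt(mean(d_drift), 0)
  expect_gt(e1071::skewness(d_drift), 0.5)
  expect_true(all(d_null == 0))
})

test_that("units sparse during whisking are excluded by the per-minute rule", {
  bouts <- tibble::tibble(onset = c(10, 40), offset = c(30, 60))  # 40 s
  sp <- dplyr::bind_rows(
    tibble::tibble(unit_id = 1L, time = seq(10.1, 59.9, by = 0.5)),  # dense
    tibble::tibble(unit_id = 2L, time = c(0.5, 35, 70)),             # rare
    tibble::tibble(unit_id = 3L, time = seq(1, 9, by = 0.1)))        # outside bouts
  expect_message(kept <- exclude_sparse_units(sp, bouts, min_rate = 2),
                 "sparse")
  expect_equal(unique(kept$unit_id), 1L)
  expect_setequal(attr(kept, "excluded_units"), c(2L, 3L))
  expect_error(exclude_sparse_units(sp, bouts[0, ]), "no whisking")
})
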