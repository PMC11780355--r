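test_that("PETH grid, bin width and flat/point responses behave", {
  expect_equal(eval(formals(compute_peth)$bin), 0.0033)
  # constant-rate unit: flat PETH at the true rate
  set.seed(5)
  dur <- 300
  sp <- tibble::tibble(unit_id = 1L, time = sort(runif(30 * dur, 0, dur)))
  onsets <- seq(10, dur - 10, by = 10)
  bouts <- tibble::tibble(onset = onsets, offset = onsets + 2)
  peth <- compute_peth(sp, bouts, t_range = c(0, dur))
  expect_equal(attr(peth, "n_trials"), length(onsets))
  expect_equal(mean(peth$rate), 30, tolerance = 0.1)
  coarse <- tapply(peth$rate, cut(peth$t, 10), mean)
  expect_true(all(abs(coarse - 30) < 3 * sqrt(30 / (length(onsets) * 0.5))))

  # one spike at onset per trial: single-bin peak at lag 0
  sp1 <- tibble::tibble(unit_id = 1L, time = onsets + 1e-4)
  p1 <- compute_peth(sp1, bouts, t_range = c(0, dur))
  peak_bin <- p1$t[which.max(p1$rate)]
  expect_lt(abs(peak_bin), 0.0033)
  expect_equal(sum(p1$rate > 0), 1)

  expect_error(compute_peth(sp, tibble::tibble(onset = 1, offset = 2),
                            t_range = c(0, 2)), "no usable bouts")
})

test_that("correlation-matrix PCA matches eigen identities and a brute-force oracle", {
  # 2 perfectly correlated units embedded with an uncorrelated third
  t <- seq(0, 1, by = 0.01)
  s <- sin(2 * pi * t)
  peth2 <- tibble::tibble(
    unit_id = rep(1:2, each = length(t)),
    t = rep(t, 2),
    rate = c(5 + s, 1 + 2 * s))
  # need >= 3 units: add a third, then check the top eigenpair dominates
  set.seed(9)
  peth3 <- dplyr::bind_rows(peth2, tibble::tibble(unit_id = 3L, t = t,
                                                  rate = rnorm(length(t))))
  pca <- pca_population(peth3)
  expect_equal(sum(pca$values), 3, tolerance = 1e-9)
  expect_gt(pca$values[1], 2 - 1e-6)
  # loadings orthonormal, sign-fixed
  V <- tidyr::pivot_wider(pca$loadings, id_cols = "unit_id", names_from = "pc",
                          values_from = "loading")
  Vm <- as.matrix(V[, -1])
  expect_equal(unname(crossprod(Vm)), diag(3), tolerance = 1e-9)
  for (j in 1:3) expect_gt(Vm[which.max(abs(Vm[, j])), j], 0)

  # random matrices vs characteristic-polynomial eigenvalues
  set.seed(10)
  for (n_u in c(4, 7, 10)) {
    X <- matrix(rnorm(400 * n_u), 400, n_u) %*%
      matrix(rnorm(n_u * n_u), n_u, n_u)
    peth <- tibble::tibble(
      unit_id = rep(seq_len(n_u), each = 400),
      t = rep(seq_len(400) * 0.01, n_u),
      rate = as.numeric(X))
    p <- pca_population(peth)
    C <- stats::cor(X)
    cp <- pracma::charpoly(C)
    lam <- sort(Re(polyroot(rev(cp))), decreasing = TRUE)
    expect_equal(p$values, lam, tolerance = 1e-8)
    expect_equal(sum(p$values), n_u, tolerance = 1e-8)
  }

  # zero-variance units are excluded with a message
  pethz <- dplyr::bind_rows(peth3, tibble::tibble(unit_id = 4L, t = t, rate = 2))
  expect_message(pz <- pca_population(pethz), "zero-variance")
  expect_equal(pz$dropped_units, 4L)
})

test_that("unexplained-variance bookkeeping is exact", {
  tt <- seq(0, 1, by = 0.01)
  set.seed(11)
  peth <- tibble::tibble(
    unit_id = rep(1:5, each = length(tt)),
    t = rep(tt, 5),
    rate = rnorm(5 * length(tt)))
  pca <- pca_population(peth)
  uv <- variance_explained_curve(pca)
  expect_equal(uv$unexplained, 1 - cumsum(pca$values) / sum(pca$values))
  expect_true(all(diff(uv$unexplained) <= 1e-12))
  expect_equal(uv$unexplained[5], 0, tolerance = 1e-12)
  # rank-1 population drops to ~0 after one component
  peth1 <- tibble::tibble(
    unit_id = rep(1:3, each = length(tt)),
    t = rep(tt, 3),
    rate = rep(sin(2 * pi * tt), 3) * rep(c(1, 2, -1), each = length(tt)))
  uv1 <- variance_explained_curve(pca_population(peth1))
  expect_lt(uv1$unexplained[1], 1e-9)
})

test_that("single-trial projections are linear in trials and zero for silent trials", {
  sim <- simulate_whisking(whisk_sim_params(duration = 80, seed = 51))
  pop <- suppressWarnings(simulate_population(
    sim, pop_sim_params(n_units = 6, baseline_rate = 20, seed = 52)))
  dur <- 80
  peth <- compute_peth(pop$spikes, sim$bouts, bin = 0.01, smooth_sd_bins = 5,
                       t_range = c(0, dur))
  pca <- pca_population(peth)
  proj_t <- project_single_trial(pop$spikes, pca, sim$bouts, bin = 0.01,
                                 smooth_sd_bins = 5, t_range = c(0, dur))
  # mean over trials ~ projection of the trial-averaged PETH
  mean_traj <- proj_t |>
    dplyr::group_by(pc, t) |>
    dplyr::summarise(value = mean(value), .groups = "drop")
  avg_proj <- dplyr::filter(pca$projections, pc <= 3)
  m <- dplyr::inner_join(mean_traj, avg_proj, by = c("pc", "t"),
                         suffix = c("_trials", "_avg"))
  expect_gt(cor(m$value_trials, m$value_avg), 0.999)

  # single trial: equals the trial-average projection of a 1-bout PETH
  b1 <- sim$bouts[2, ]
  peth1 <- compute_peth(pop$spikes, b1, bin = 0.01, smooth_sd_bins = 5,
                        t_range = c(0, dur))
  pca1 <- pca_population(peth1)
  pr1 <- project_single_trial(pop$spikes, pca1, b1, bin = 0.01,
                              smooth_sd_bins = 5, t_range = c(0, dur))
  cmp <- dplyr::inner_join(pr1, dplyr::filter(pca1$projections, pc <= 3),
                           by = c("pc", "t"), suffix = c("_st", "_avg"))
  expect_equal(cmp$value_st, cmp$value_avg, tolerance = 1e-6)

  # all-zero trial projects to an identically zero trajectory
  late_bout <- dplyr::filter(sim$bouts, onset > 10)[1, ]
  sp_far <- dplyr::filter(pop$spikes, time < 1)   # no spikes near this bout
  sp_far <- dplyr::bind_rows(sp_far,
                             tibble::tibble(unit_id = pca$units, time = 0.01))
  pr0 <- project_single_trial(sp_far, pca, late_bout, bin = 0.01,
                              smooth_sd_bins = 5, t_range = c(0, dur))
  expect_lt(max(abs(pr0$value)), 1e-9)

  expect_error(project_single_trial(dplyr::filter(pop$spikes, unit_id < 3),
                                    pca, sim$bouts, t_range = c(0, dur)),
               "lacks units")
})

test_that("cross-correlation recovers constructed lags with the lead-positive convention", {
  tt <- seq(0, 10, by = 0.005)
  n_t <- length(tt)
  base <- sin(2 * pi * 0.7 * tt) * exp(-(tt - 5)^2 / 4)
  shift_by <- function(x, k) whiskpop:::shift_pad(x, k)
  whisk <- tibble::tibble(t = tt, mean_angle = base)
  mk_proj <- function(v1) {
    tibble::tibble(t = rep(tt, 3), pc = rep(1:3, each = n_t),
                   value = c(v1, rnorm(n_t), rnorm(n_t)))
  }
  set.seed(33)
  # neural copy of behavior shifted 40 ms earlier -> peak_lag = +0.040
  lead <- mk_proj(shift_by(base, 8))     # 8 bins * 5 ms
  xc <- crosscorr_pc_whisking(lead, whisk, max_lag = 0.5)
  expect_equal(xc$peaks$peak_lag[xc$peaks$pc == 1], 0.040, tolerance = 1e-9)
  # lagging copy -> negative peak lag
  lagp <- mk_proj(shift_by(base, -8))
  xc2 <- crosscorr_pc_whisking(lagp, whisk, max_lag = 0.5)
  expect_equal(xc2$peaks$peak_lag[xc2$peaks$pc == 1], -0.040, tolerance = 1e-9)
  # self-correlation: peak value 1 at lag 0 (normalization anchor)
  self <- mk_proj(base)
  xc3 <- crosscorr_pc_whisking(self, whisk, max_lag = 0.5)
  expect_equal(xc3$peaks$peak_lag[xc3$peaks$pc == 1], 0)
  expect_equal(abs(xc3$peaks$peak_value[xc3$peaks$pc == 1]), 1)
  expect_true(all(abs(xc3$xcorr$value[xc3$xcorr$pc == 1]) <= 1 + 1e-12))
  # constant inputs rejected
  expect_error(crosscorr_pc_whisking(self, tibble::tibble(t = tt, mean_angle = 1)),
               "constant")
})

test_that("peak-lag t test matches hand arithmetic and calibrates under the null", {
  res <- peak_lag_test(c(1, 2, 3))
  expect_equal(res$statistic, 2 * sqrt(3), tolerance = 1e-9)
  expect_equal(res$mean, 2)
  expect_warning(z <- peak_lag_test(rep(0, 5)), "zero variance")
  expect_true(is.na(z$statistic))
  expect_error(peak_lag_test(c(1, 2)), ">= 3")
  # type-I error near nominal
  set.seed(19)
  rej <- mean(replicate(2000, peak_lag_test(rnorm(10))$p.value < 0.05))
  expect_gt(rej, 0.03); expect_lt(rej, 0.07)
})

test_that("loading kurtosis has the right analytic anchors", {
  set.seed(23)
  mk <- function(x) tibble::tibble(pc = 1, loading = x)
  expect_lt(abs(loading_kurtosis(mk(rnorm(1e5)), pcs = 1)$excess_kurtosis), 0.05)
  expect_equal(loading_kurtosis(mk(runif(1e5)), pcs = 1)$excess_kurtosis,
               -1.2, tolerance = 0.05)
  lap <- rexp(1e5) * sample(c(-1, 1), 1e5, replace = TRUE)
  expect_equal(loading_kurtosis(mk(lap), pcs = 1)$excess_kurtosis,
               3, tolerance = 0.3)
  # per-recording option
  df <- tibble::tibble(recording = rep(1:2, each = 50), pc = 1,
                       loading = rnorm(100))
  expect_equal(nrow(loading_kurtosis(df, pcs = 1, by = "recording")), 2)
})

test_that("distributed vs outlier-driven components show the expected kurtosis pattern", {
  set.seed(29)
  tt <- seq(0, 2, by = 0.005)
  n_t <- length(tt)
  shared <- sin(2 * pi * tt)
  spike2 <- cos(2 * pi * 3 * tt)
  n_u <- 60
  rates <- vapply(seq_len(n_u), function(u) {
    w <- rnorm(1)                      # distributed, centered contributions
    r <- w * shared + 1.5 * rnorm(n_t)
    if (u <= 2) r <- r + 8 * spike2 * c(1, -1)[u]   # 2 outlier units
    r
  }, numeric(n_t))
  peth <- tibble::tibble(unit_id = rep(seq_len(n_u), each = n_t),
                         t = rep(tt, n_u), rate = as.numeric(rates))
  pca <- pca_population(peth)
  k <- loading_kurtosis(pca$loadings, pcs = 1:2)
  # the outlier-pair component concentrates loading mass on 2 units
  expect_gt(max(k$excess_kurtosis), 3)
  # the distributed component stays near normal kurtosis
  expect_lt(min(abs(k$excess_kurtosis)), 1.2)
})

test_that("set-point decoding is exact for linear targets and null for noise", {
  set.seed(41)
  trials <- 1:6
  tt <- seq(-2, 3, by = 0.05)
  proj <- purrr::map_dfr(trials, function(tr) {
    tibble::tibble(trial = tr, t = rep(tt, 3), pc = rep(1:3, each = length(tt)),
                   value = rnorm(3 * length(tt)))
  })
  w <- c(2, -1, 0.5)
  sp_lin <- proj |>
    tidyr::pivot_wider(id_cols = c("trial", "t"), names_from = "pc",
                       values_from = "value", names_prefix = "pc") |>
    dplyr::mutate(setpoint = 10 + pc1 * w[1] + pc2 * w[2] + pc3 * w[3]) |>
    dplyr::select(trial, t, setpoint)
  dec <- decode_setpoint(proj, sp_lin, seed = 2)
  expect_equal(dec$r2_test, 1, tolerance = 1e-9)
  expect_equal(unname(dec$weights[-1]), w, tolerance = 1e-9)
  expect_true(all(dec$predictions$lo <= dec$predictions$predicted + 1e-9))
  # pure-noise components cannot decode
  sp_noise <- dplyr::mutate(sp_lin, setpoint = rnorm(dplyr::n()))
  dec0 <- decode_setpoint(proj, sp_noise, seed = 2)
  expect_lt(dec0$r2_test, 0.2)
})
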