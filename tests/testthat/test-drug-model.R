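test_that("binning and normalization scale counts to the -5 min bin", {
  meta <- list(recording = "r1", animal = "a1", condition = "Veh",
               drop_time = 1200, baseline_minutes = 20)
  # constant-rate recording: all normalized values ~ 1
  set.seed(3)
  sp <- tibble::tibble(unit_id = 1L, time = sort(runif(120000, 0, 4500)))
  pan <- bin_and_normalize(sp, meta)
  expect_equal(pan$s[pan$bin_min == -5], 1)
  expect_true(all(abs(pan$s - 1) < 0.1))
  expect_equal(pan$period, ifelse(pan$bin_min < 0, "pre", "post"))
  expect_true(pan$period[pan$bin_min == 0] == "post")
  expect_equal(pan$time_index[pan$bin_min == 0], 1)

  # rate doubling after the drop: post bins ~ 2
  sp2 <- tibble::tibble(unit_id = 1L, time = sort(c(runif(30000, 0, 1200),
                                                    runif(165000, 1200, 4500))))
  pan2 <- bin_and_normalize(sp2, meta)
  expect_equal(mean(pan2$s[pan2$period == "post"]), 2, tolerance = 0.1)

  # zero reference count: recording excluded with a warning
  sp3 <- tibble::tibble(unit_id = 1L, time = c(10, 2000))
  expect_warning(pan3 <- bin_and_normalize(sp3, meta), "excluded")
  expect_equal(nrow(pan3), 0)
  expect_error(bin_and_normalize(sp, modifyList(meta, list(baseline_minutes = 5))),
               "2 pre bins")
})

test_that("time kernel decays with distance, is PSD, and exposes the literal form", {
  bins <- seq(0, 40, by = 5)
  K <- build_time_kernel(bins)
  expect_true(all(abs(diag(K) - (1 + 1e-6)) < 1e-12))
  expect_true(isSymmetric(K))
  expect_gt(K["0", "5"], K["0", "10"])   # closer pairs correlate more
  expect_silent(chol(K))                  # 9x9 Cholesky succeeds
  expect_error(build_time_kernel(5), ">= 2")
  expect_warning(KL <- build_time_kernel(bins, form = "literal"), "increases")
  expect_lt(KL["0", "5"], KL["0", "40"])  # the printed composition grows
})

test_that("model log density matches hand-checkable structure", {
  pan <- simulate_count_panel(panel_sim_params(seed = 7))
  th <- pan$truth$theta
  ld <- count_model_logdensity(pan$panel, th)
  expect_true(is.finite(ld))
  # compiled posterior used by the sampler agrees with the reference density
  K <- build_time_kernel(seq(0, 40, by = 5))
  dat <- whiskpop:::make_model_data(pan$panel, whisk_count_priors(), K)
  v <- c(th$a0, th$b0, th$ac, th$bc, th$aa, th$ba, th$at, th$bt)
  expect_equal(whiskpop:::.cm_posterior(v, dat)$lp, ld, tolerance = 1e-10)
  # compiled gradient agrees with finite differences
  g <- whiskpop:::.cm_posterior(v, dat)$grad
  idx <- c(1, 2, 5, 30, 60, length(v))
  gn <- vapply(idx, function(j) {
    h <- 1e-6; vp <- v; vm <- v; vp[j] <- v[j] + h; vm[j] <- v[j] - h
    (whiskpop:::.cm_posterior(vp, dat)$lp -
        whiskpop:::.cm_posterior(vm, dat)$lp) / (2 * h)
  }, numeric(1))
  expect_equal(g[idx], gn, tolerance = 1e-5)
})

test_that("HMC and JAGS sample the same posterior", {
  pan <- simulate_count_panel(panel_sim_params(seed = 3))
  fit_h <- fit_count_model(pan$panel, chains = 2, warmup = 300, iter = 500,
                           seed = 11)
  fit_j <- fit_count_model(pan$panel, method = "jags", chains = 1,
                           adapt = 1000, warmup = 2000, iter = 10000, seed = 11)
  dh <- fit_h$draws[, "th_ac[2]"] - fit_h$draws[, "th_ac[1]"]
  dj <- fit_j$draws[, "th_ac[2]"] - fit_j$draws[, "th_ac[1]"]
  # agreement up to Monte Carlo error of the slow-mixing reference chain
  expect_lt(abs(mean(dh) - mean(dj)), 0.06)
  expect_lt(abs(sd(dh) - sd(dj)) / sd(dj), 0.3)
  expect_gt(fit_h$diagnostics$accept_rate, 0.6)
  expect_false(is.na(fit_h$diagnostics$rhat_max))
  expect_error(fit_count_model(dplyr::mutate(pan$panel, s = s - min(s))),
               "positive")
})

test_that("prior-predictive counts live on the scale of observed counts", {
  # prior draws produce normalized counts of order one, including extremes
  draws <- purrr::map_dfr(1:5, function(i) {
    simulate_count_panel(panel_sim_params(seed = 600 + i))$panel
  })
  expect_gt(mean(draws$s > 0.2 & draws$s < 10), 0.8)
  expect_gt(max(draws$s), 2)
})

test_that("posterior predictive checks are calibrated for self-generated data", {
  pan <- simulate_count_panel(panel_sim_params(seed = 17))
  fit <- fit_count_model(pan$panel, chains = 1, warmup = 300, iter = 400,
                         seed = 5)
  ppc <- posterior_predictive_check(fit, n_draws = 150, seed = 1)
  expect_equal(dplyr::n_distinct(ppc$replicates$draw), 150)
  expect_equal(nrow(ppc$replicates), 150 * nrow(pan$panel))
  # data from the model itself: no extreme discrepancies
  expect_true(all(ppc$stats$p_value > 0.005 & ppc$stats$p_value < 0.995))
  # deliberately misspecified data: heavy lognormal flagged
  pan_mis <- pan$panel
  set.seed(2)
  pan_mis$s <- exp(rnorm(nrow(pan_mis), 0, 2.5))
  fit_mis <- fit_count_model(pan_mis, chains = 1, warmup = 300, iter = 400,
                             seed = 5)
  ppc_mis <- posterior_predictive_check(fit_mis, n_draws = 150, seed = 1)
  expect_true(any(ppc_mis$stats$p_value < 0.01 | ppc_mis$stats$p_value > 0.99))
})

test_that("condition contrasts and their differences obey draw-wise identities", {
  pan <- simulate_count_panel(panel_sim_params(seed = 19))
  fit <- fit_count_model(pan$panel, chains = 1, warmup = 300, iter = 400,
                         seed = 7)
  ctr <- condition_contrasts(fit)
  expect_setequal(unique(ctr$summary$parameter),
                  c("alpha", "beta", "mean", "variance"))
  expect_true(all(ctr$summary$hdi_lower <= ctr$summary$hdi_upper))
  expect_true(all(ctr$summary$frac_defined >= 0 & ctr$summary$frac_defined <= 1))
  # forcing identical pre/post draws zeroes the contrast
  fit0 <- fit
  fit0$draws[, "th_ac[2]"] <- fit0$draws[, "th_ac[1]"]
  fit0$draws[, "th_bc[2]"] <- fit0$draws[, "th_bc[1]"]
  ctr0 <- condition_contrasts(fit0)
  z <- dplyr::filter(ctr0$summary, condition == "GlyT2-CNO")
  expect_equal(z$contrast, rep(0, 4), tolerance = 1e-12)
  # antisymmetry of contrast differences
  d_ab <- contrast_differences(ctr, "GlyT2-CNO", "WT-CNO")
  d_ba <- contrast_differences(ctr, "WT-CNO", "GlyT2-CNO")
  expect_equal(d_ab$difference, -d_ba$difference)
  expect_equal(d_ab$hdi_lower, -d_ba$hdi_upper)
  expect_error(contrast_differences(ctr, "GlyT2-CNO", "nope"), "unknown")
  # tidy/glance surfaces
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "hdi_lower") %in% names(td)))
  expect_equal(glance(fit)$n_obs, nrow(pan$panel))
})

test_that("highest-density intervals are shortest intervals at the given mass", {
  set.seed(31)
  x <- rnorm(20000)
  h <- hdi(x, 0.94)
  expect_equal(unname(h[2] - h[1]), 2 * qnorm(0.97), tolerance = 0.05)
  # skewed sample: HDI shorter than the central interval
  y <- rexp(20000)
  hy <- hdi(y, 0.94)
  ci <- quantile(y, c(0.03, 0.97))
  expect_lt(hy[2] - hy[1], ci[2] - ci[1])
  expect_equal(unname(hy[1]), 0, tolerance = 0.01)
})
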