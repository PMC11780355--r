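# Small shared fixtures, built once per test run.

fix_sim <- simulate_whisking(whisk_sim_params(duration = 60, seed = 42))

fix_pop <- suppressWarnings(simulate_population(
  fix_sim, pop_sim_params(n_units = 8, baseline_rate = 10, tuning_gain = 0.3,
                          seed = 43)))

# pure sinusoid trace for analytic checks
fix_sine_trace <- function(A = 12, B = 30, f = 8, duration = 30, fs = 299) {
  t <- seq(0, duration, by = 1 / fs)
  tibble::tibble(time = t, angle = B + A * sin(2 * pi * f * t))
}

# tuning-curve tibble from explicit per-bin rates (11 bins unless stated)
fix_curve <- function(rates, unit_id = 1L, occupied = rates >= 0) {
  n <- length(rates)
  tibble::tibble(
    unit_id = unit_id, bin = seq_len(n),
    angle_lo = seq_len(n) - 1, angle_hi = seq_len(n), angle_mid = seq_len(n) - 0.5,
    rate = rates, rate_se = 0,
    occupancy = ifelse(occupied, 1 / sum(occupied), 0),
    n_timebins = ifelse(occupied, 10L, 0L), sparse = all(rates == 0)
  )
}

# independent inverse-Gamma + model joint density, computed by a different
# route than the package (Gamma density of the reciprocal plus Jacobian;
# eigendecomposition-based multivariate normal)
oracle_count_logdensity <- function(panel, th, pr = whisk_count_priors(),
                                    K = NULL) {
  conds <- intersect(c("GlyT2-CNO", "WT-CNO", "Veh"), unique(panel$condition))
  if (length(conds) == 0) conds <- sort(unique(panel$condition))
  cp <- match(panel$condition, conds) * 2L - ifelse(panel$period == "pre", 1L, 0L)
  an <- match(panel$animal, sort(unique(panel$animal)))
  nt <- length(th$at)
  atf <- c(0, th$at); btf <- c(0, th$bt)
  tb <- ifelse(is.na(panel$time_index), 1L, panel$time_index + 1L)
  al <- exp(th$a0 + th$ac[cp] + th$aa[an] + atf[tb])
  be <- exp(th$b0 + th$bc[cp] + th$ba[an] + btf[tb])
  ll <- sum(stats::dgamma(1 / panel$s, shape = al, rate = be, log = TRUE) -
              2 * log(panel$s))
  if (is.null(K)) K <- exp(-0.7 * abs(outer(seq_len(nt), seq_len(nt), "-"))) +
      1e-6 * diag(nt)
  mv <- function(x, mu, S) {
    ev <- eigen(S, symmetric = TRUE)
    -0.5 * (length(x) * log(2 * pi) + sum(log(ev$values)) +
              sum((t(ev$vectors) %*% (x - mu))^2 / ev$values))
  }
  ll +
    sum(stats::dnorm(c(th$a0, th$ac, th$aa), pr$mu_alpha, pr$sigma_alpha, log = TRUE)) +
    sum(stats::dnorm(c(th$b0, th$bc, th$ba), pr$mu_beta, pr$sigma_beta, log = TRUE)) +
    mv(th$at, pr$mu_alpha, pr$sigma_alpha^2 * K) +
    mv(th$bt, pr$mu_beta, pr$sigma_beta^2 * K)
}

# random coefficient set of the panel's dimensions
random_theta <- function(n_cond = 3, n_animal = 17, n_time = 9) {
  list(a0 = rnorm(1, 1, 0.5), b0 = rnorm(1, 1.2, 0.5),
       ac = rnorm(2 * n_cond, 1, 0.5), bc = rnorm(2 * n_cond, 1.2, 0.5),
       aa = rnorm(n_animal, 1, 0.5), ba = rnorm(n_animal, 1.2, 0.5),
       at = rnorm(n_time, 1, 0.5), bt = rnorm(n_time, 1.2, 0.5))
}
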