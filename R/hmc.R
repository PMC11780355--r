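# Hamiltonian Monte Carlo for the hierarchical inverse-Gamma count model.
# The posterior is smooth but contains a prior-limited redundancy ridge
# (intercept vs condition vs animal vs time coefficients) which defeats
# single-site samplers; gradient-based proposals traverse it efficiently.
# The log posterior, gradient and leapfrog trajectories are computed in
# compiled code (src/count_model.cpp); this file holds the chain logic:
# dual-averaged step size (target acceptance 0.8), diagonal mass matrix
# adapted mid-warmup, jittered path length.

# Coefficient-vector layout shared with the compiled code:
# [a0, b0, ac(ncp), bc(ncp), aa(nan), ba(nan), at(nt), bt(nt)]
theta_layout <- function(ix) {
  n <- c(a0 = 1L, b0 = 1L, ac = ix$n_cp, bc = ix$n_cp,
         aa = ix$n_an, ba = ix$n_an, at = ix$n_time, bt = ix$n_time)
  ends <- cumsum(n)
  starts <- ends - n + 1L
  purrr::map2(starts, ends, function(s, e) s:e)
}

# Data list consumed by the compiled posterior.
make_model_data <- function(panel, priors, kernel) {
  ix <- panel_indices(panel)
  pr <- priors
  Sa <- pr$sigma_alpha^2 * kernel
  Sb <- pr$sigma_beta^2 * kernel
  list(
    log_s = log(panel$s), inv_s = 1 / panel$s,
    cp = as.integer(ix$cp), an = as.integer(ix$an), tb = as.integer(ix$tb),
    ncp = ix$n_cp, nan = ix$n_an, nt = ix$n_time,
    mu_a = pr$mu_alpha, mu_b = pr$mu_beta,
    prec_a = 1 / pr$sigma_alpha^2, prec_b = 1 / pr$sigma_beta^2,
    Kinv_a = solve(Sa), Kinv_b = solve(Sb),
    ldet_a = as.numeric(determinant(Sa)$modulus) +
      ix$n_time * log(2 * pi),
    ldet_b = as.numeric(determinant(Sb)$modulus) +
      ix$n_time * log(2 * pi)
  )
}

# One HMC chain. Returns a draws matrix (iter x dim) plus acceptance info.
hmc_chain <- function(data, dim, iter, warmup, init, leapfrog = 24,
                      target_accept = 0.8, seed = 1L) {
  set.seed(seed)
  v <- init
  mass <- rep(1 / 0.2^2, dim)    # ~ inverse prior variance to start
  inv_mass <- 1 / mass
  eps <- 0.02
  # dual averaging (Hoffman & Gelman 2014 scheme)
  mu_da <- log(10 * eps); log_eps_bar <- log(eps); H_bar <- 0
  gamma_da <- 0.05; t0 <- 10; kappa <- 0.75
  draws <- matrix(NA_real_, iter, dim)
  warm_buf <- matrix(NA_real_, warmup, dim)
  lp <- .cm_posterior(v, data)$lp
  accept_n <- 0
  L_lo <- max(2L, round(0.8 * leapfrog)); L_hi <- round(1.2 * leapfrog)
  for (m in seq_len(warmup + iter)) {
    p0 <- stats::rnorm(dim, 0, sqrt(mass))
    ke0 <- 0.5 * sum(p0^2 * inv_mass)
    L <- sample(L_lo:L_hi, 1)
    tr <- .cm_trajectory(v, p0, eps, L, inv_mass, data)
    dH <- (tr$lp - tr$ke) - (lp - ke0)
    a_prob <- if (is.finite(dH)) min(1, exp(dH)) else 0
    if (stats::runif(1) < a_prob) {
      v <- tr$theta; lp <- tr$lp
      if (m > warmup) accept_n <- accept_n + 1
    }
    if (m <= warmup) {
      warm_buf[m, ] <- v
      frac <- 1 / (m + t0)
      H_bar <- (1 - frac) * H_bar + frac * (target_accept - a_prob)
      log_eps <- mu_da - sqrt(m) / gamma_da * H_bar
      w <- m^(-kappa)
      log_eps_bar <- w * log_eps + (1 - w) * log_eps_bar
      eps <- exp(log_eps)
      if (m == floor(warmup / 2) && m > 20) {
        vr <- apply(warm_buf[floor(m / 2):m, , drop = FALSE], 2, stats::var)
        mass <- 1 / pmax(vr, 1e-6); inv_mass <- 1 / mass
        mu_da <- log(10 * eps)     # re-anchor the step-size search
        H_bar <- 0
      }
      if (m == warmup) eps <- exp(log_eps_bar)
    } else {
      draws[m - warmup, ] <- v
    }
  }
  list(draws = draws, accept_rate = accept_n / iter, step_size = eps)
}

fit_count_model_hmc <- function(panel, priors, kernel, chains, warmup, iter,
                                seed, leapfrog = 24) {
  data <- make_model_data(panel, priors, kernel)
  ix <- panel_indices(panel)
  layout <- theta_layout(ix)
  dim <- max(layout[[length(layout)]])
  alpha_side <- unlist(purrr::imap(layout, function(idx, nm) {
    rep(nm %in% c("a0", "ac", "aa", "at"), length(idx))
  }), use.names = FALSE)
  prior_mean <- ifelse(alpha_side, priors$mu_alpha, priors$mu_beta)

  res <- purrr::map(seq_len(chains), function(ch) {
    set.seed(seed + 17L * ch)
    init <- prior_mean + stats::rnorm(dim, 0, 0.05)
    hmc_chain(data, dim, iter = iter, warmup = warmup, init = init,
              leapfrog = leapfrog, seed = seed + 17L * ch + 1L)
  })
  nm <- c("th_a0", "th_b0",
          sprintf("th_ac[%d]", seq_len(ix$n_cp)),
          sprintf("th_bc[%d]", seq_len(ix$n_cp)),
          sprintf("th_aa[%d]", seq_len(ix$n_an)),
          sprintf("th_ba[%d]", seq_len(ix$n_an)),
          sprintf("th_at[%d]", seq_len(ix$n_time)),
          sprintf("th_bt[%d]", seq_len(ix$n_time)))
  chains_mcmc <- lapply(res, function(r) {
    colnames(r$draws) <- nm
    coda::mcmc(r$draws)
  })
  list(mcmc = coda::mcmc.list(chains_mcmc),
       accept = vapply(res, `[[`, numeric(1), "accept_rate"),
       step_size = vapply(res, `[[`, numeric(1), "step_size"))
}
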