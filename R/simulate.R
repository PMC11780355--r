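# Synthetic-data generators. These define the study conditions for every test
# in the package: bout-structured whisking traces, tracked-landmark series,
# heterogeneously tuned Poisson spike populations whose shared component leads
# behavior, and multi-recording normalized spike-count panels drawn from the
# hierarchical inverse-Gamma generative model.

#' Parameters for the whisking-trace generator
#'
#' @param duration Recording length, s.
#' @param frame_rate Video rate, Hz (default 299).
#' @param bout_rate Whisking-bout rate, bouts/min.
#' @param bout_duration Mean bout duration, s (gamma-distributed, shape 4).
#' @param whisk_freq Whisking oscillation frequency, Hz (~8 Hz in mice;
#'   configurable, not asserted).
#' @param amplitude_rest,amplitude_whisk Oscillation envelope at rest and
#'   during bouts, deg. `amplitude_whisk >= amplitude_rest >= 0`.
#' @param setpoint_base Resting set point, deg.
#' @param setpoint_whisk_shift Set-point protraction during bouts, deg.
#' @param setpoint_drift_sd Stationary SD of the slow Ornstein-Uhlenbeck
#'   set-point drift, deg.
#' @param setpoint_tau OU time constant, s.
#' @param onset_ramp Envelope rise/fall time at bout edges, s.
#' @param noise_sd Additive frame noise, deg.
#' @param seed Integer seed; identical seeds give identical traces.
#' @return A list of class `whisk_sim_params`.
#' @export
whisk_sim_params <- function(duration = 120, frame_rate = 299, bout_rate = 6,
                             bout_duration = 2, whisk_freq = 8,
                             amplitude_rest = 1, amplitude_whisk = 18,
                             setpoint_base = 20, setpoint_whisk_shift = 6,
                             setpoint_drift_sd = 2, setpoint_tau = 5,
                             onset_ramp = 0.15, noise_sd = 0.5, seed = 1L) {
  if (duration <= 0 || frame_rate <= 0) {
    rlang::abort("duration and frame_rate must be positive")
  }
  if (!(amplitude_whisk >= amplitude_rest && amplitude_rest >= 0)) {
    rlang::abort("need amplitude_whisk >= amplitude_rest >= 0")
  }
  structure(as.list(environment()), class = "whisk_sim_params")
}

#' Simulate a bout-structured whisking trace
#'
#' Whisker azimuthal angle modeled as an amplitude-modulated sinusoid riding on
#' a slowly drifting set point. Bouts arrive as a Poisson process (non-
#' overlapping, >= 1 s apart); during a bout the envelope ramps from
#' `amplitude_rest` to `amplitude_whisk` and the set point protracts by
#' `setpoint_whisk_shift`. Ground-truth amplitude, set point and bout table are
#' returned alongside the trace.
#'
#' @param params A [whisk_sim_params()] object.
#' @return A list of class `whisk_sim` with elements `trace` (tibble
#'   `time`, `angle`), `truth` (tibble `time`, `amplitude`, `setpoint`,
#'   `whisking`), `bouts` (tibble `onset`, `offset`) and `params`.
#' @export
simulate_whisking <- function(params = whisk_sim_params()) {
  stopifnot(inherits(params, "whisk_sim_params"))
  p <- params
  set.seed(p$seed)
  n <- round(p$duration * p$frame_rate)
  t <- (seq_len(n) - 1) / p$frame_rate

  bouts <- draw_bout_table(p$duration, p$bout_rate, p$bout_duration,
                           edge = 3, min_gap = 1)

  # envelope activation r(t) in [0, 1] with raised-cosine edges; the ramp
  # starts AT onset so the protraction growth is phase-coherent across bouts
  # (no incoherent pre-onset oscillation enters onset-aligned averages)
  r <- numeric(n)
  ramp <- max(p$onset_ramp, 1e-6)
  for (i in seq_len(nrow(bouts))) {
    on <- bouts$onset[i]; off <- bouts$offset[i]
    idx <- t >= on & t <= off + ramp
    u <- pmin(1, pmax(0, pmin((t[idx] - on) / ramp,
                              ((off + ramp) - t[idx]) / ramp)))
    r[idx] <- pmax(r[idx], (1 - cos(pi * u)) / 2)
  }

  amplitude <- p$amplitude_rest + (p$amplitude_whisk - p$amplitude_rest) * r
  drift <- ou_path(n, 1 / p$frame_rate, p$setpoint_tau, p$setpoint_drift_sd)
  setpoint <- p$setpoint_base + drift + p$setpoint_whisk_shift * r
  # whisking cycles phase-lock to bout onset: each bout starts protracting
  # from rest, as real bouts do
  t_last_onset <- numeric(n)
  if (nrow(bouts) > 0) {
    idx <- findInterval(t, bouts$onset)
    t_last_onset <- ifelse(idx >= 1, t - bouts$onset[pmax(idx, 1)], t)
  } else {
    t_last_onset <- t
  }
  phase <- 2 * pi * p$whisk_freq * t_last_onset - pi / 2
  angle <- setpoint + amplitude * sin(phase) +
    if (p$noise_sd > 0) stats::rnorm(n, 0, p$noise_sd) else 0

  structure(list(
    trace = tibble::tibble(time = t, angle = angle),
    truth = tibble::tibble(time = t, amplitude = amplitude,
                           setpoint = setpoint, whisking = r > 0.5),
    bouts = bouts,
    params = p
  ), class = "whisk_sim")
}

# Poisson bout process with non-overlap and a minimum gap; overlapping
# candidates are re-drawn, rarely dropped.
draw_bout_table <- function(duration, bout_rate, bout_duration,
                            edge = 3, min_gap = 1) {
  n_b <- stats::rpois(1, bout_rate * duration / 60)
  if (n_b == 0 || duration <= 2 * edge) {
    return(tibble::tibble(onset = numeric(0), offset = numeric(0)))
  }
  ons <- numeric(0); offs <- numeric(0)
  for (b in seq_len(n_b)) {
    placed <- FALSE
    for (try in 1:200) {
      on <- stats::runif(1, edge, duration - edge)
      dur <- stats::rgamma(1, shape = 4, rate = 4 / bout_duration)
      off <- min(on + dur, duration - edge / 2)
      if (all(on > offs + min_gap | off < ons - min_gap)) {
        ons <- c(ons, on); offs <- c(offs, off); placed <- TRUE; break
      }
    }
    if (!placed) rlang::inform("bout dropped: no non-overlapping slot found")
  }
  o <- order(ons)
  tibble::tibble(onset = ons[o], offset = offs[o])
}

# Ornstein-Uhlenbeck path with stationary SD `sigma` and time constant `tau`.
ou_path <- function(n, dt, tau, sigma) {
  if (sigma <= 0) return(numeric(n))
  a <- exp(-dt / tau)
  innov_sd <- sigma * sqrt(1 - a^2)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sigma)
  for (i in 2:n) x[i] <- a * x[i - 1] + stats::rnorm(1, 0, innov_sd)
  x
}

#' Simulate tracked whisker landmarks from an angle trace
#'
#' Places four collinear markers along a straight whisker whose first segment
#' (basal marker to second marker) makes the trace's angle with the horizontal
#' through the basal marker. Image coordinates with y increasing downward;
#' protraction (increasing angle) moves markers up the image. This is the
#' inverse of [compute_whisker_angle()] up to pixel noise.
#'
#' @param trace Data frame with `time` and `angle` (deg).
#' @param segment_length Marker spacing along the whisker, px (> 0).
#' @param base Basal marker image coordinates `c(x, y)`, px.
#' @param pixel_noise Isotropic Gaussian jitter per marker, px.
#' @param whisker Bodypart name prefix (default `"C3"`).
#' @param seed Integer seed for the noise.
#' @return Tidy tibble: `frame`, `time`, `bodypart`, `x`, `y`, `likelihood`.
#' @export
simulate_landmarks <- function(trace, segment_length = 100, base = c(250, 250),
                               pixel_noise = 0, whisker = "C3", seed = 1L) {
  if (segment_length <= 0) rlang::abort("segment_length must be positive")
  stopifnot(all(is.finite(trace$angle)))
  set.seed(seed)
  th <- trace$angle * pi / 180
  n <- nrow(trace)
  out <- purrr::map_dfr(0:3, function(k) {
    tibble::tibble(
      frame = seq_len(n) - 1L,
      time = trace$time,
      bodypart = sprintf("%s_%d", whisker, k + 1L),
      x = base[1] + k * segment_length * cos(th),
      y = base[2] - k * segment_length * sin(th),
      likelihood = 1
    )
  })
  if (pixel_noise > 0) {
    out$x <- out$x + stats::rnorm(nrow(out), 0, pixel_noise)
    out$y <- out$y + stats::rnorm(nrow(out), 0, pixel_noise)
  }
  dplyr::arrange(out, .data$frame, .data$bodypart)
}

#' Parameters for the tuned-population spike generator
#'
#' @param n_units Number of units (>= 0).
#' @param baseline_rate Mean baseline rate, Hz (per-unit rates are
#'   gamma-heterogeneous around this).
#' @param tuning_gain Tuning strength, Hz per deg of angle deviation.
#' @param prop_ramp Fraction of units with monotonic ramp tuning; the rest get
#'   Gaussian-bump tuning at a preferred angle.
#' @param preferred_angles Optional vector of preferred angles (deg) for bump
#'   units; sampled uniformly over the angle range when `NULL`.
#' @param tuning_width Bump-unit tuning width (Gaussian SD) as a fraction of
#'   the recording's angle range (default 0.25).
#' @param neural_lead Lead of the population component relative to behavior, s
#'   (positive = neural activity anticipates the whisker; default 0.040).
#' @param peak_jitter_sd Per-unit SD of the lead, s.
#' @param transient_gain Extra rate at whisking onset, Hz (gives units a
#'   defined response peak near bout onset).
#' @param transient_width SD of the onset transient, s.
#' @param drug_gain Multiplicative rate factor after `drop_time`.
#' @param seed Integer seed.
#' @return A list of class `pop_sim_params`.
#' @export
pop_sim_params <- function(n_units = 30, baseline_rate = 6, tuning_gain = 0.6,
                           prop_ramp = 0.5, preferred_angles = NULL,
                           tuning_width = 0.25,
                           neural_lead = 0.040, peak_jitter_sd = 0,
                           transient_gain = 12, transient_width = 0.12,
                           drug_gain = 1, seed = 1L) {
  if (n_units < 0) rlang::abort("n_units must be >= 0")
  if (baseline_rate < 0 || transient_gain < 0) rlang::abort("rates must be >= 0")
  if (!is.finite(neural_lead)) rlang::abort("neural_lead must be finite")
  structure(as.list(environment()), class = "pop_sim_params")
}

#' Simulate a tuned spike population driven by a whisking trace
#'
#' Each unit fires as an inhomogeneous Poisson process whose rate is a
#' baseline plus a tuning function of the whisker angle evaluated
#' `neural_lead + jitter_i` seconds in the future (the population anticipates
#' behavior), plus a Gaussian transient at each bout onset (similarly
#' advanced). After `drop_time` all rates are multiplied by `drug_gain`.
#' Negative instantaneous rates are clipped at zero with a warning.
#'
#' @param sim A `whisk_sim` object from [simulate_whisking()] (its ground-truth
#'   bout table drives the onset transients).
#' @param params A [pop_sim_params()] object.
#' @param drop_time Drug-drop time, s (`NA` for none).
#' @return A list of class `pop_sim`: `spikes` (tibble `unit_id`, `time`),
#'   `units` (ground-truth tuning per unit) and `params`.
#' @export
simulate_population <- function(sim, params = pop_sim_params(), drop_time = NA) {
  stopifnot(inherits(sim, "whisk_sim"), inherits(params, "pop_sim_params"))
  p <- params
  set.seed(p$seed)
  trace <- sim$trace
  fs <- sim$params$frame_rate
  n <- nrow(trace)
  dt <- 1 / fs

  if (p$n_units == 0) {
    return(structure(list(
      spikes = tibble::tibble(unit_id = integer(0), time = numeric(0)),
      units = tibble::tibble(unit_id = integer(0)),
      params = p
    ), class = "pop_sim"))
  }

  rng <- range(trace$angle)
  mid <- mean(rng); span <- max(diff(rng), 1e-9)
  units <- tibble::tibble(
    unit_id = seq_len(p$n_units),
    shape = ifelse(stats::runif(p$n_units) < p$prop_ramp, "ramp", "bump"),
    sign = sample(c(-1, 1), p$n_units, replace = TRUE),
    baseline = stats::rgamma(p$n_units, shape = 4, rate = 4 / max(p$baseline_rate, 1e-9)),
    gain = p$tuning_gain * stats::runif(p$n_units, 0.5, 1.5),
    pref = if (is.null(p$preferred_angles)) stats::runif(p$n_units, rng[1], rng[2])
           else rep_len(p$preferred_angles, p$n_units),
    lead = p$neural_lead + stats::rnorm(p$n_units, 0, p$peak_jitter_sd)
  )

  onsets <- sim$bouts$onset
  clipped <- 0L
  spikes <- purrr::map_dfr(seq_len(p$n_units), function(i) {
    u <- units[i, ]
    # rate over frame [t, t + dt) is emitted at t + dt/2 on average; sampling
    # the angle at t + lead + dt/2 makes spikes lead the angle by exactly
    # `lead`
    ang <- stats::approx(trace$time, trace$angle,
                         xout = trace$time + u$lead + dt / 2, rule = 2)$y
    tune <- if (u$shape == "ramp") {
      u$sign * u$gain * (ang - mid)
    } else {
      u$gain * span / 2 * exp(-(ang - u$pref)^2 / (2 * (span * p$tuning_width)^2))
    }
    rate <- u$baseline + tune
    if (p$transient_gain > 0 && length(onsets) > 0) {
      tr <- numeric(n)
      for (on in onsets) {
        c0 <- on - u$lead - dt / 2
        idx <- which(abs(trace$time - c0) < 4 * p$transient_width)
        tr[idx] <- tr[idx] +
          exp(-(trace$time[idx] - c0)^2 / (2 * p$transient_width^2))
      }
      rate <- rate + p$transient_gain * tr
    }
    if (!is.na(drop_time) && p$drug_gain != 1) {
      rate <- rate * ifelse(trace$time >= drop_time, p$drug_gain, 1)
    }
    neg <- rate < 0
    if (any(neg)) { clipped <<- clipped + sum(neg); rate[neg] <- 0 }
    counts <- stats::rpois(n, rate * dt)
    nz <- which(counts > 0)
    times <- rep(trace$time[nz], counts[nz]) + stats::runif(sum(counts[nz]), 0, dt)
    tibble::tibble(unit_id = u$unit_id, time = sort(times))
  })
  if (clipped > 0) {
    rlang::warn(sprintf("negative instantaneous rates clipped at 0 in %d frames", clipped))
  }
  structure(list(spikes = spikes, units = units, params = p),
            class = "pop_sim")
}

#' Parameters for the spike-count panel generator
#'
#' Defines the design of the chemogenetic experiment panel: recordings per
#' condition (default 19 GlyT2-CNO / 5 WT-CNO / 9 Veh), animals (two
#' recordings per animal, 17 animals at the default design), 5-min bins with
#' `pre_bins` baseline bins and 9 post bins, and the true coefficients of the
#' generative model. Coefficients are drawn from the model priors (Gaussian,
#' time effects from the decaying-covariance multivariate normal) unless
#' supplied; planted condition effects are injected via `contrast_alpha` /
#' `contrast_beta` (post = pre + contrast).
#'
#' @param n_recordings Named counts per condition.
#' @param pre_bins Number of 5-min baseline bins (the last is the -5 min bin).
#' @param post_bins Number of post bins (time-coefficient levels), default 9.
#' @param bin_width Bin width, min (default 5).
#' @param decay Kernel decay constant (default 0.7).
#' @param theta Optional full coefficient list (`a0`, `b0`, `ac`, `bc`, `aa`,
#'   `ba`, `at`, `bt`); drawn from the priors when `NULL`.
#' @param contrast_alpha,contrast_beta Optional named per-condition planted
#'   post-minus-pre contrasts for the shape/scale condition coefficients.
#' @param priors Hyperprior list from [whisk_count_priors()].
#' @param seed Integer seed.
#' @return A list of class `panel_sim_params`.
#' @export
panel_sim_params <- function(n_recordings = c("GlyT2-CNO" = 19, "WT-CNO" = 5, "Veh" = 9),
                             pre_bins = 4, post_bins = 9, bin_width = 5,
                             decay = 0.7, theta = NULL,
                             contrast_alpha = NULL, contrast_beta = NULL,
                             priors = whisk_count_priors(), seed = 1L) {
  if (pre_bins < 1 || post_bins < 1) rlang::abort("need >= 1 pre and post bin")
  structure(as.list(environment()), class = "panel_sim_params")
}

#' Simulate a normalized spike-count panel from the generative model
#'
#' Draws `s ~ Inverse-Gamma(alpha, beta)` for every (recording, bin) cell with
#' `alpha` and `beta` from the exact log-linked linear predictors (intercept +
#' condition-by-period + animal + post-bin time effects), time effects drawn
#' from the multivariate normal with the decaying time kernel. Ground truth is
#' retained for recovery tests. Cells whose true `alpha <= 1` have no finite
#' mean (and `alpha <= 2` no finite variance); a warning flags panels where
#' moment-based checks would be undefined, and the truth table carries
#' `mean_defined` / `var_defined` flags.
#'
#' @param params A [panel_sim_params()] object.
#' @return A list of class `panel_sim`: `panel` (tibble `recording`, `animal`,
#'   `condition`, `bin_min`, `period`, `time_index`, `s`), `truth` (list with
#'   `theta` and the per-cell `alpha`, `beta` tibble) and `params`.
#' @export
simulate_count_panel <- function(params = panel_sim_params()) {
  stopifnot(inherits(params, "panel_sim_params"))
  p <- params
  set.seed(p$seed)
  pr <- p$priors
  conds <- names(p$n_recordings)
  n_rec <- sum(p$n_recordings)
  condition <- rep(conds, p$n_recordings)
  n_animal <- ceiling(n_rec / 2)
  animal <- rep(seq_len(n_animal), each = 2)[seq_len(n_rec)]

  bins <- seq(-p$pre_bins * p$bin_width, (p$post_bins - 1) * p$bin_width,
              by = p$bin_width)
  design <- tidyr::expand_grid(recording = seq_len(n_rec), bin_min = bins) |>
    dplyr::mutate(
      condition = condition[.data$recording],
      animal = animal[.data$recording],
      period = ifelse(.data$bin_min < 0, "pre", "post"),
      time_index = ifelse(.data$bin_min < 0, NA_integer_,
                          as.integer(.data$bin_min / p$bin_width + 1L))
    )

  K <- build_time_kernel(seq(0, by = p$bin_width, length.out = p$post_bins),
                         bin_width = p$bin_width, decay = p$decay)
  theta <- p$theta %||% draw_theta_from_priors(conds, n_animal, K, pr)
  theta <- plant_contrasts(theta, conds, p$contrast_alpha, p$contrast_beta)

  cp <- match(condition[design$recording], conds) * 2L -
    ifelse(design$period == "pre", 1L, 0L)
  at_full <- c(0, theta$at); bt_full <- c(0, theta$bt)
  tb <- ifelse(is.na(design$time_index), 1L, design$time_index + 1L)
  alpha <- exp(theta$a0 + theta$ac[cp] + theta$aa[design$animal] + at_full[tb])
  beta <- exp(theta$b0 + theta$bc[cp] + theta$ba[design$animal] + bt_full[tb])
  if (any(alpha <= 2)) {
    rlang::warn(sprintf(
      "%d cells have alpha <= 2: variance (alpha <= 2) or mean (alpha <= 1) undefined for moment-based checks",
      sum(alpha <= 2)
    ))
  }
  s <- 1 / stats::rgamma(nrow(design), shape = alpha, rate = beta)

  panel <- dplyr::mutate(design, s = s) |>
    dplyr::select("recording", "animal", "condition", "bin_min", "period",
                  "time_index", "s")
  truth_cells <- dplyr::mutate(design, alpha = alpha, beta = beta,
                               mean_defined = alpha > 1,
                               var_defined = alpha > 2)
  structure(list(panel = panel,
                 truth = list(theta = theta, cells = truth_cells, kernel = K),
                 params = p),
            class = "panel_sim")
}

# Draw the full coefficient set from the model priors; condition-by-period
# coefficients are ordered (cond1-pre, cond1-post, cond2-pre, ...).
draw_theta_from_priors <- function(conds, n_animal, K, pr) {
  L <- t(chol(K))
  nc <- 2L * length(conds)
  list(
    a0 = stats::rnorm(1, pr$mu_alpha, pr$sigma_alpha),
    b0 = stats::rnorm(1, pr$mu_beta, pr$sigma_beta),
    ac = stats::rnorm(nc, pr$mu_alpha, pr$sigma_alpha),
    bc = stats::rnorm(nc, pr$mu_beta, pr$sigma_beta),
    aa = stats::rnorm(n_animal, pr$mu_alpha, pr$sigma_alpha),
    ba = stats::rnorm(n_animal, pr$mu_beta, pr$sigma_beta),
    at = as.numeric(pr$mu_alpha + pr$sigma_alpha * (L %*% stats::rnorm(nrow(K)))),
    bt = as.numeric(pr$mu_beta + pr$sigma_beta * (L %*% stats::rnorm(nrow(K))))
  )
}

plant_contrasts <- function(theta, conds, contrast_alpha, contrast_beta) {
  for (cn in names(contrast_alpha)) {
    i <- match(cn, conds)
    theta$ac[2 * i] <- theta$ac[2 * i - 1] + contrast_alpha[[cn]]
  }
  for (cn in names(contrast_beta)) {
    i <- match(cn, conds)
    theta$bc[2 * i] <- theta$bc[2 * i - 1] + contrast_beta[[cn]]
  }
  theta
}
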