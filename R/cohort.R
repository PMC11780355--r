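# Cohort-level synthetic experiments: paired pre/post recordings with
# condition-specific changes in neural peak jitter and whisking onset
# velocity, analyzed end-to-end through the PETH / peak-time / slope
# pipeline.

#' Simulate a pre/post recording pair for the onset analyses
#'
#' One recording: a pre-drug and a post-drug session, each a whisking trace
#' plus a tuned spike population. The post session changes the per-unit peak
#' jitter (`jitter_post`) and scales the whisking protraction vigor
#' (oscillation amplitude and set-point shift) by `slope_mult`, so the
#' onset-velocity slope scales accordingly. Population defaults emphasize the
#' whisking-onset transient (the quantity the peak-time analysis reads out).
#'
#' @param jitter_pre,jitter_post Per-unit SD of the neural lead, s.
#' @param slope_mult Post/pre onset-velocity ratio.
#' @param duration Session length, s.
#' @param n_units Units per recording.
#' @param seed Integer seed.
#' @param whisk_args,pop_args Overrides passed to [whisk_sim_params()] /
#'   [pop_sim_params()].
#' @return List with `pre` and `post`, each holding `sim` (a `whisk_sim`)
#'   and `pop` (a `pop_sim`).
#' @export
simulate_onset_recording <- function(jitter_pre = 0.05, jitter_post = 0.05,
                                     slope_mult = 1, duration = 240,
                                     n_units = 30, seed = 1L,
                                     whisk_args = list(), pop_args = list()) {
  session <- function(jitter, mult, s) {
    wp <- do.call(whisk_sim_params, utils::modifyList(
      list(duration = duration, seed = s,
           amplitude_whisk = 18 * mult,
           setpoint_whisk_shift = 6 * mult), whisk_args))
    sim <- simulate_whisking(wp)
    pp <- do.call(pop_sim_params, utils::modifyList(
      list(n_units = n_units, baseline_rate = 8, tuning_gain = 0.15,
           transient_gain = 25, transient_width = 0.08,
           peak_jitter_sd = jitter, seed = s + 1L),
      pop_args))
    list(sim = sim, pop = suppressWarnings(simulate_population(sim, pp)))
  }
  list(pre = session(jitter_pre, 1, seed),
       post = session(jitter_post, slope_mult, seed + 1000L))
}

#' Simulate a condition cohort for the onset analyses
#'
#' A cohort of paired pre/post recordings emulating the two experimental
#' patterns. `"glyt2"`: post-drop peak jitter halved in every recording
#' (consistent tightening of neural timing) while the onset-velocity change
#' is drawn with inflated variance and mixed sign, independent of the neural
#' change — neural and behavioral effects decouple. `"control"`: small
#' correlated changes — a single per-recording latent drives both a mild
#' jitter change and a proportional velocity change.
#'
#' @param condition `"control"` or `"glyt2"`.
#' @param n_recordings Recordings in the cohort (defaults: 12 control / 13
#'   GlyT2).
#' @param jitter Baseline per-unit peak jitter SD, s (default 0.05).
#' @param seed Integer seed.
#' @param ... Passed to [simulate_onset_recording()].
#' @return List of class `onset_cohort` with one element per recording plus
#'   attributes `condition` and `truth` (per-recording planted parameters).
#' @export
simulate_onset_cohort <- function(condition = c("control", "glyt2"),
                                  n_recordings = NULL, jitter = 0.05,
                                  seed = 1L, ...) {
  condition <- match.arg(condition)
  n <- n_recordings %||% if (condition == "control") 12L else 13L
  set.seed(seed)
  if (condition == "control") {
    u <- stats::rnorm(n)
    jitter_post <- jitter * (1 + 0.3 * u)
    slope_mult <- 1 + 0.06 * u + stats::rnorm(n, 0, 0.01)
  } else {
    jitter_post <- rep(jitter / 2, n)
    slope_mult <- 1 + 0.5 * stats::rnorm(n)
  }
  jitter_post <- pmax(jitter_post, 0.005)
  slope_mult <- pmax(slope_mult, 0.25)
  recs <- purrr::map(seq_len(n), function(i) {
    simulate_onset_recording(jitter_pre = jitter, jitter_post = jitter_post[i],
                             slope_mult = slope_mult[i],
                             seed = seed + 100L * i, ...)
  })
  structure(recs, class = "onset_cohort", condition = condition,
            truth = tibble::tibble(recording = seq_len(n),
                                   jitter_pre = jitter,
                                   jitter_post = jitter_post,
                                   slope_mult = slope_mult))
}

#' Analyze an onset cohort end-to-end
#'
#' Runs every recording through the onset pipeline — bout-aligned whisker
#' average, PETH, peak-time dispersion, protraction slope — using each
#' session's ground-truth bout table for alignment, and collects the
#' per-recording summaries.
#'
#' @param cohort An `onset_cohort` from [simulate_onset_cohort()].
#' @param peth_bin PETH bin width, s.
#' @param smooth_sd_bins PETH smoothing for peak-picking, bins.
#' @return Tibble, one row per recording: the [summarize_onset()] columns
#'   plus `recording` and `condition`.
#' @export
analyze_onset_cohort <- function(cohort, peth_bin = 0.0033,
                                 smooth_sd_bins = 20) {
  purrr::imap_dfr(cohort, function(rec, i) {
    one <- function(ses) {
      dur <- ses$sim$params$duration
      avg <- trial_average_whisking(ses$sim$trace, ses$sim$bouts)
      peth <- compute_peth(ses$pop$spikes, ses$sim$bouts, bin = peth_bin,
                           t_range = c(0, dur))
      list(avg = avg, peth = peth)
    }
    pre <- one(rec$pre); post <- one(rec$post)
    dplyr::mutate(
      summarize_onset(pre$peth, post$peth, pre$avg, post$avg,
                      smooth_sd_bins = smooth_sd_bins),
      recording = as.integer(i),
      condition = attr(cohort, "condition"),
      .before = 1
    )
  })
}

#' Condition-level onset statistics from cohort summaries
#'
#' Applies the three onset tests to analyzed cohorts: the paired Wilcoxon
#' dispersion test within each cohort, Levene's test of slope-contrast
#' variance between cohorts, and the neural-behavioral coupling correlation
#' within each cohort.
#'
#' @param control,glyt2 Summary tibbles from [analyze_onset_cohort()].
#' @return List: `dispersion` (tibble, per condition), `levene` (tibble),
#'   `coupling` (tibble, per condition).
#' @export
onset_cohort_tests <- function(control, glyt2) {
  disp <- dplyr::bind_rows(
    dplyr::mutate(dispersion_test(control$peak_sd_pre, control$peak_sd_post),
                  condition = "control", .before = 1),
    dplyr::mutate(dispersion_test(glyt2$peak_sd_pre, glyt2$peak_sd_post),
                  condition = "glyt2", .before = 1)
  )
  lev <- slope_variance_test(control$slope_contrast, glyt2$slope_contrast)
  coup <- dplyr::bind_rows(
    dplyr::mutate(coupling_correlation(control$delta_sd, control$slope_contrast),
                  condition = "control", .before = 1),
    dplyr::mutate(coupling_correlation(glyt2$delta_sd, glyt2$slope_contrast),
                  condition = "glyt2", .before = 1)
  )
  list(dispersion = disp, levene = lev, coupling = coup)
}
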