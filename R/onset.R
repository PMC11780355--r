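# Movement-onset analyses: dispersion of PETH peak times, whisking
# protraction slopes, their pre/post-drug statistical tests, and
# neural-behavioral coupling.

#' Per-unit PETH peak times around whisking onset
#'
#' For every unit, the time of the absolute peak of the (optionally smoothed)
#' baseline-subtracted trial-averaged activity within a window around
#' whisking onset (default -0.7 to 1.3 s, focusing on the initial protraction
#' period). Baseline is the mean rate over `baseline_window`; the peak is the
#' maximum of the magnitude of the baseline-subtracted rate, earliest time on
#' exact ties. Units flat inside the window are excluded with a message.
#'
#' @param peth PETH tibble from [compute_peth()].
#' @param window Peak-search window, s.
#' @param baseline_window Baseline window, s (default -2 to -1 s).
#' @param smooth_sd_bins Gaussian smoothing SD in bins before peak-picking.
#' @return Tibble `unit_id`, `peak_time` (s), `peak_value` (Hz, baseline
#'   subtracted).
#' @export
peth_peak_times <- function(peth, window = c(-0.7, 1.3),
                            baseline_window = c(-2, -1), smooth_sd_bins = 20) {
  res <- peth |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::group_map(function(df, key) {
      df <- dplyr::arrange(df, .data$t)
      r <- if (smooth_sd_bins > 0) gaussian_smooth(df$rate, smooth_sd_bins)
           else df$rate
      bl <- mean(r[df$t >= baseline_window[1] & df$t <= baseline_window[2]])
      if (!is.finite(bl)) bl <- 0
      inw <- df$t >= window[1] & df$t <= window[2]
      y <- abs(r[inw] - bl)
      if (diff(range(y)) == 0) {
        return(tibble::tibble(unit_id = key$unit_id, peak_time = NA_real_,
                              peak_value = NA_real_))
      }
      i <- which.max(y)   # which.max returns the earliest maximum
      tibble::tibble(unit_id = key$unit_id, peak_time = df$t[inw][i],
                     peak_value = (r[inw] - bl)[i])
    }) |>
    dplyr::bind_rows()
  n_flat <- sum(is.na(res$peak_time))
  if (n_flat > 0) {
    rlang::inform(sprintf("%d unit(s) flat in the peak window; excluded", n_flat))
  }
  dplyr::filter(res, !is.na(.data$peak_time))
}

#' Paired pre/post test of peak-time dispersion
#'
#' Two-sided Wilcoxon signed-rank test of the per-recording standard
#' deviations of PETH peak times, pre versus post drug. The reported `T` is
#' the smaller of the positive- and negative-rank sums (all differences of
#' one sign give `T = 0`); ties at zero difference are dropped. All pairs
#' equal is degenerate and returns `NA` statistics with a warning.
#'
#' @param sd_pre,sd_post Paired per-recording peak-time SDs, s.
#' @return Tibble `T`, `p.value`, `n`, `n_used`.
#' @export
dispersion_test <- function(sd_pre, sd_post) {
  stopifnot(length(sd_pre) == length(sd_post))
  d <- sd_post - sd_pre
  nz <- d != 0
  if (!any(nz)) {
    rlang::warn("all pairs equal; signed-rank test degenerate")
    return(tibble::tibble(T = NA_real_, p.value = NA_real_,
                          n = length(d), n_used = 0L))
  }
  r <- rank(abs(d[nz]))
  T_stat <- min(sum(r[d[nz] > 0]), sum(r[d[nz] < 0]))
  wt <- suppressWarnings(stats::wilcox.test(sd_post, sd_pre, paired = TRUE))
  tibble::tibble(T = T_stat, p.value = wt$p.value,
                 n = length(d), n_used = sum(nz))
}

#' Slope of the average whisker trace at movement onset
#'
#' Least-squares line through the bout-averaged whisker position inside a
#' window around onset (default -0.06 to 0.21 s), whose slope is a proxy for
#' protraction velocity.
#'
#' @param avg Tibble `t`, `mean_angle` from [trial_average_whisking()].
#' @param window Fit window, s.
#' @return Tibble `slope` (deg/s), `slope_se`, `intercept`, `r_squared`, `n`.
#' @export
fit_onset_slope <- function(avg, window = c(-0.06, 0.21)) {
  sel <- avg$t >= window[1] & avg$t <= window[2]
  if (sum(sel) < 3) rlang::abort("average trace does not cover the fit window")
  fit <- stats::lm(mean_angle ~ t, data = avg[sel, ])
  sm <- suppressWarnings(summary(fit))   # exact fits trip a summary warning
  tibble::tibble(slope = unname(coef(fit)[2]),
                 slope_se = sm$coefficients[2, 2],
                 intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared, n = sum(sel))
}

#' Levene test for unequal slope-contrast variances
#'
#' Levene's test (median-centered by default, i.e. Brown-Forsythe) of whether
#' the post-minus-pre protraction-slope contrasts have different spread in
#' two groups of recordings.
#'
#' @param contrasts_a,contrasts_b Slope contrasts per recording, deg/s
#'   (>= 3 each).
#' @param center `"median"` (default) or `"mean"`.
#' @return Tibble `W`, `p.value`, `df1`, `df2`.
#' @export
slope_variance_test <- function(contrasts_a, contrasts_b,
                                center = c("median", "mean")) {
  center <- match.arg(center)
  if (length(contrasts_a) < 3 || length(contrasts_b) < 3) {
    rlang::abort("need >= 3 recordings per group")
  }
  x <- c(contrasts_a, contrasts_b)
  g <- factor(rep(c("a", "b"), c(length(contrasts_a), length(contrasts_b))))
  lt <- car::leveneTest(x, g, center = if (center == "median") stats::median else mean)
  tibble::tibble(W = lt$`F value`[1], p.value = lt$`Pr(>F)`[1],
                 df1 = lt$Df[1], df2 = lt$Df[2])
}

#' Coupling between neural-timing and behavioral changes
#'
#' Squared Pearson correlation between the per-recording change in PETH
#' peak-time dispersion and the whisking slope contrast. High coupling means
#' neural and behavioral changes move together across recordings.
#'
#' @param delta_sd Per-recording change in peak-time SD (post minus pre), s.
#' @param slope_contrast Per-recording slope contrast (post minus pre),
#'   deg/s.
#' @return Tibble `r_squared`, `r`, `n`.
#' @export
coupling_correlation <- function(delta_sd, slope_contrast) {
  stopifnot(length(delta_sd) == length(slope_contrast))
  if (length(delta_sd) < 3) rlang::abort("need >= 3 paired recordings")
  r <- stats::cor(delta_sd, slope_contrast)
  tibble::tibble(r_squared = r^2, r = r, n = length(delta_sd))
}

#' Movement-onset summary of one recording (pre and post periods)
#'
#' Convenience wrapper producing the per-recording quantities entering the
#' onset tests: peak-time SD pre/post, onset slope pre/post, and their
#' contrasts. Recordings whose trial-averaged whisker trace is flat in the
#' onset window (range below `min_whisk_range` deg) are flagged poor-whisking
#' and return `NA` slopes.
#'
#' @param peth_pre,peth_post PETH tibbles for the two periods.
#' @param avg_pre,avg_post Bout-averaged whisker traces for the two periods.
#' @param peak_window,slope_window Analysis windows, s.
#' @param smooth_sd_bins PETH smoothing for peak-picking.
#' @param min_whisk_range Poor-whisking threshold, deg.
#' @return One-row tibble: `peak_sd_pre`, `peak_sd_post`, `delta_sd`,
#'   `slope_pre`, `slope_post`, `slope_contrast`, `poor_whisking`.
#' @export
summarize_onset <- function(peth_pre, peth_post, avg_pre, avg_post,
                            peak_window = c(-0.7, 1.3),
                            slope_window = c(-0.06, 0.21),
                            smooth_sd_bins = 20, min_whisk_range = 2) {
  sd_of <- function(peth) {
    stats::sd(peth_peak_times(peth, peak_window,
                              smooth_sd_bins = smooth_sd_bins)$peak_time)
  }
  flat <- function(avg) {
    sel <- avg$t >= slope_window[1] & avg$t <= slope_window[2]
    diff(range(avg$mean_angle[sel])) < min_whisk_range
  }
  poor <- flat(avg_pre) || flat(avg_post)
  slope <- function(avg) {
    if (poor) NA_real_ else fit_onset_slope(avg, slope_window)$slope
  }
  sp <- slope(avg_pre); so <- slope(avg_post)
  sd_pre <- sd_of(peth_pre); sd_post <- sd_of(peth_post)
  tibble::tibble(peak_sd_pre = sd_pre, peak_sd_post = sd_post,
                 delta_sd = sd_post - sd_pre,
                 slope_pre = sp, slope_post = so, slope_contrast = so - sp,
                 poor_whisking = poor)
}
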