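# ggplot2 graphics for each result type.

#' Plot a whisking decomposition
#'
#' Whisker angle with the Hilbert amplitude and set point overlaid and
#' detected bouts shaded.
#'
#' @param kin Tibble from [decompose_whisking()].
#' @param bouts Optional bout table.
#' @return A ggplot object.
#' @export
plot_whisking <- function(kin, bouts = NULL) {
  p <- ggplot2::ggplot(kin, ggplot2::aes(x = .data$time))
  if (!is.null(bouts) && nrow(bouts) > 0) {
    p <- p + ggplot2::geom_rect(
      data = bouts,
      ggplot2::aes(xmin = .data$onset, xmax = .data$offset,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "grey85")
  }
  p +
    ggplot2::geom_line(ggplot2::aes(y = .data$angle), linewidth = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$setpoint), colour = "brown") +
    ggplot2::geom_line(ggplot2::aes(y = .data$setpoint + .data$amplitude),
                       colour = "steelblue", linetype = 2) +
    ggplot2::labs(x = "time (s)", y = "whisker angle (deg)",
                  title = "Whisker angle, set point and amplitude envelope")
}

#' Plot single-unit tuning curves
#'
#' Firing rate over whisker-position bins per unit, with the occupancy
#' (fraction of time per position) overlaid.
#'
#' @param curves Tibble from [compute_tuning_curve()].
#' @param units Units to display (default: first 8).
#' @return A ggplot object.
#' @export
plot_tuning <- function(curves, units = NULL) {
  units <- units %||% utils::head(sort(unique(curves$unit_id)), 8)
  df <- dplyr::filter(curves, .data$unit_id %in% units)
  occ_scale <- max(df$rate) / max(df$occupancy + 1e-12)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$angle_mid)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$rate), fill = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$rate - .data$rate_se,
                                        ymax = .data$rate + .data$rate_se),
                           width = 0) +
    ggplot2::geom_line(ggplot2::aes(y = .data$occupancy * occ_scale),
                       colour = "steelblue") +
    ggplot2::facet_wrap(~unit_id, scales = "free_y") +
    ggplot2::labs(x = "whisker angle (deg)", y = "rate (Hz)",
                  title = "Tuning to whisker position (blue: occupancy)")
}

#' Plot a PETH matrix as a heatmap
#'
#' @param peth Tibble from [compute_peth()].
#' @return A ggplot object.
#' @export
plot_peth <- function(peth) {
  ggplot2::ggplot(peth, ggplot2::aes(x = .data$t, y = factor(.data$unit_id),
                                     fill = .data$rate)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time from whisking onset (s)", y = "unit",
                  fill = "rate (Hz)")
}

#' @export
autoplot.pop_pca <- function(object, pcs = 1:3, ...) {
  proj <- dplyr::filter(object$projections, .data$pc %in% pcs)
  ggplot2::ggplot(proj, ggplot2::aes(x = .data$t, y = .data$value,
                                     colour = factor(.data$pc))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from whisking onset (s)", y = "projection (a.u.)",
                  colour = "pc",
                  title = sprintf("Population trajectories (pc1 explains %.0f%%)",
                                  100 * object$var_explained$prop[1]))
}

#' @export
autoplot.pc_xcorr <- function(object, ...) {
  ggplot2::ggplot(object$xcorr,
                  ggplot2::aes(x = .data$lag, y = .data$value,
                               colour = factor(.data$pc))) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = object$peaks,
                        ggplot2::aes(xintercept = .data$peak_lag,
                                     colour = factor(.data$pc)),
                        linetype = 2) +
    ggplot2::labs(x = "lag (s; positive = neural leads)",
                  y = "normalized cross-correlation", colour = "pc")
}

#' @export
autoplot.contrast_summary <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$condition, y = .data$contrast)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$hdi_lower,
                                          ymax = .data$hdi_upper)) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(y = sprintf("post - pre contrast (%d%% hdi)",
                              round(100 * object$prob)),
                  x = NULL)
}

#' @export
autoplot.setpoint_decoder <- function(object, trials = NULL, ...) {
  df <- object$predictions
  if (!is.null(trials)) df <- dplyr::filter(df, .data$trial %in% trials)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "red", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$actual), colour = "brown") +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted), colour = "red") +
    ggplot2::facet_wrap(~trial) +
    ggplot2::labs(x = "time from whisking onset (s)", y = "set point (deg)",
                  title = sprintf("Set-point reconstruction (held-out R^2 = %.2f)",
                                  object$r2_test))
}

#' @export
autoplot.count_model_ppc <- function(object, panel_s = NULL, ...) {
  p <- ggplot2::ggplot(object$replicates, ggplot2::aes(x = .data$s_rep)) +
    ggplot2::geom_density(ggplot2::aes(group = .data$draw),
                          colour = "grey80", linewidth = 0.1) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "normalized spike count",
                  title = "Posterior predictive check")
  if (!is.null(panel_s)) {
    p <- p + ggplot2::geom_density(
      data = tibble::tibble(s = panel_s),
      ggplot2::aes(x = .data$s), inherit.aes = FALSE, colour = "black")
  }
  p
}
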