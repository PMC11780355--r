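# End-to-end pipeline runner: chains kinematics -> tuning -> population ->
# onset (and optionally the count-model fit) on real exports or on a
# freshly simulated session, writing tidy CSV/JSON outputs plus a run log.

#' Run the analysis pipeline end-to-end
#'
#' Stages: load or simulate a session; whisker angle and Hilbert
#' decomposition; bout detection; tuning curves, entropy and spline/k-means
#' taxonomy; bout-aligned PETH, PCA and neural-behavioral cross-correlation;
#' onset peak times and protraction slope; optionally the hierarchical
#' count-model fit on a simulated multi-recording panel. Each stage's outputs
#' are written as tidy CSV/JSON under `out_dir` together with `run_log.txt`
#' (package version, seed, per-stage status). A stage failure raises a
#' structured error naming the stage; outputs of completed stages are kept.
#' Sessions whose whisking is absent (no detected bouts) skip the tuning,
#' population and onset stages with a documented exclusion in
#' `exclusions.json`.
#'
#' @param config Path to a YAML configuration file, or an equivalent named
#'   list. Recognized sections: `seed`; `simulate` (arguments of
#'   [whisk_sim_params()] plus `n_units` and other [pop_sim_params()]
#'   fields); `paths` (`landmarks` CSV and `spikes_dir` for real exports,
#'   plus `frame_rate`); `kinematics` (`band`, `setpoint_cutoff`,
#'   `threshold`, `min_bout`, `min_gap`); `tuning` (`time_bin`, `n_bins`,
#'   `k`); `population` (`window`, `bin`, `smooth_sd_bins`, `max_lag`);
#'   `onset`; `drugfit` (`enabled`, [panel_sim_params()] fields, MCMC
#'   settings).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed overriding the config's.
#' @return Invisibly, a named list with every stage's in-memory result.
#' @export
run_whisk_pipeline <- function(config, out_dir, seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  seed <- seed %||% cfg$seed %||% 1L
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  log_line <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"), sprintf(...)),
        file = log_path, append = TRUE)
  }
  cat(sprintf("whiskpop %s | R %s | seed %d\n",
              as.character(utils::packageVersion("whiskpop")),
              paste(R.version$major, R.version$minor, sep = "."), seed),
      file = log_path)
  results <- list()
  stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e) {
      log_line("stage %s FAILED: %s", name, conditionMessage(e))
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)),
                   class = "whiskpop_pipeline_error")
    })
    log_line("stage %s ok", name)
    out
  }

  # --- session: simulate or read -------------------------------------------
  results$session <- stage("session", {
    if (!is.null(cfg$simulate)) {
      sc <- cfg$simulate
      wp_args <- sc[names(sc) %in% names(formals(whisk_sim_params))]
      wp <- do.call(whisk_sim_params, utils::modifyList(wp_args,
                                                        list(seed = seed)))
      sim <- simulate_whisking(wp)
      pp_args <- sc[names(sc) %in% names(formals(pop_sim_params))]
      pp <- do.call(pop_sim_params, utils::modifyList(pp_args,
                                                      list(seed = seed + 1L)))
      pop <- simulate_population(sim, pp, drop_time = sc$drop_time %||% NA)
      list(trace = sim$trace, spikes = pop$spikes, simulated = TRUE,
           duration = wp$duration)
    } else {
      fr <- cfg$paths$frame_rate %||% 299
      lmks <- read_dlc_landmarks(cfg$paths$landmarks, frame_rate = fr)
      trace <- compute_whisker_angle(lmks)
      spikes <- read_phy_spikes(cfg$paths$spikes_dir)
      list(trace = trace, spikes = spikes[, c("unit_id", "time")],
           simulated = FALSE, duration = max(trace$time))
    }
  })
  trace <- results$session$trace
  spikes <- results$session$spikes

  # --- kinematics ----------------------------------------------------------
  kc <- cfg$kinematics %||% list()
  results$kinematics <- stage("kinematics", {
    kin <- decompose_whisking(trace,
                              band = unlist(kc$band %||% c(4, 25)),
                              setpoint_cutoff = kc$setpoint_cutoff %||% 4)
    bouts <- detect_whisking_bouts(kin,
                                   threshold = kc$threshold %||% 10,
                                   min_bout = kc$min_bout %||% 0.5,
                                   min_gap = kc$min_gap %||% 0.25)
    readr::write_csv(kin, file.path(out_dir, "kinematics.csv"))
    write_bout_table(bouts, file.path(out_dir, "bouts.csv"))
    list(kin = kin, bouts = bouts)
  })
  bouts <- results$kinematics$bouts

  window <- unlist((cfg$population %||% list())$window %||% c(-2, 3))
  usable <- sum(bouts$onset + window[1] >= min(trace$time) &
                bouts$onset + window[2] <= max(trace$time))
  if (nrow(bouts) == 0 || usable < 2) {
    jsonlite::write_json(
      list(excluded_stages = c("tuning", "population", "onset"),
           reason = "absent or poor whisking: fewer than 2 usable bouts"),
      file.path(out_dir, "exclusions.json"), auto_unbox = TRUE)
    log_line("tuning/population/onset skipped: absent whisking (%d usable bouts)",
             usable)
    return(invisible(results))
  }

  # --- tuning --------------------------------------------------------------
  tc <- cfg$tuning %||% list()
  results$tuning <- stage("tuning", {
    curves <- compute_tuning_curve(spikes, trace,
                                   time_bin = tc$time_bin %||% 0.033,
                                   n_bins = tc$n_bins %||% 11)
    ent <- tuning_entropy(curves)
    sm <- smooth_tuning(curves)
    k <- tc$k %||% 8
    clusters <- if (length(unique(curves$unit_id)) >= k) {
      cluster_tuning(sm, k = k, seed = seed)
    }
    readr::write_csv(curves, file.path(out_dir, "tuning_curves.csv"))
    readr::write_csv(ent, file.path(out_dir, "tuning_entropy.csv"))
    if (!is.null(clusters)) {
      readr::write_csv(clusters$labels, file.path(out_dir, "tuning_clusters.csv"))
    }
    list(curves = curves, entropy = ent, spline = sm, clusters = clusters)
  })

  # --- population ----------------------------------------------------------
  pcfg <- cfg$population %||% list()
  results$population <- stage("population", {
    peth <- compute_peth(spikes, bouts, window = window,
                         bin = pcfg$bin %||% 0.0033,
                         t_range = c(0, results$session$duration))
    pca <- pca_population(peth)
    grid <- sort(unique(peth$t))
    avg <- trial_average_whisking(trace, bouts, window = window, grid = grid)
    proj3 <- dplyr::filter(pca$projections, .data$pc <= 3) |>
      dplyr::mutate(value = as.numeric(
        gaussian_smooth_by(.data$value, .data$pc, pcfg$smooth_sd_bins %||% 20)))
    xc <- crosscorr_pc_whisking(proj3, avg[, c("t", "mean_angle")],
                                max_lag = pcfg$max_lag %||% 1)
    readr::write_csv(tibble::tibble(pc = seq_along(pca$values),
                                    eigenvalue = pca$values),
                     file.path(out_dir, "pca_eigenvalues.csv"))
    readr::write_csv(pca$loadings, file.path(out_dir, "pca_loadings.csv"))
    readr::write_csv(xc$peaks, file.path(out_dir, "xcorr_peaks.csv"))
    jsonlite::write_json(as.list(glance(pca)),
                         file.path(out_dir, "pca_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    list(peth = peth, pca = pca, avg = avg, xcorr = xc)
  })

  # --- onset ---------------------------------------------------------------
  results$onset <- stage("onset", {
    peaks <- peth_peak_times(results$population$peth)
    slope <- fit_onset_slope(results$population$avg)
    out <- list(peak_time_sd = stats::sd(peaks$peak_time),
                onset_slope = slope$slope, n_units = nrow(peaks))
    jsonlite::write_json(out, file.path(out_dir, "onset_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    readr::write_csv(peaks, file.path(out_dir, "peth_peaks.csv"))
    c(out, list(peaks = peaks))
  })

  # --- drug-effect model (optional) ----------------------------------------
  dc <- cfg$drugfit %||% list()
  if (isTRUE(dc$enabled)) {
    results$drugfit <- stage("drugfit", {
      ps_args <- dc[names(dc) %in% names(formals(panel_sim_params))]
      ps <- do.call(panel_sim_params, utils::modifyList(ps_args,
                                                        list(seed = seed)))
      panel <- simulate_count_panel(ps)$panel
      fit <- fit_count_model(panel, chains = dc$chains %||% 2,
                             adapt = dc$adapt %||% 500,
                             warmup = dc$warmup %||% 500,
                             iter = dc$iter %||% 500, seed = seed)
      ctr <- condition_contrasts(fit)
      readr::write_csv(ctr$summary, file.path(out_dir, "drug_contrasts.csv"))
      jsonlite::write_json(as.list(glance(fit)),
                           file.path(out_dir, "drugfit_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      list(fit = fit, contrasts = ctr)
    })
  }
  log_line("pipeline complete")
  invisible(results)
}

# Smooth a long (value, group) vector group-wise.
gaussian_smooth_by <- function(value, group, sd_bins) {
  unlist(lapply(split(value, group), gaussian_smooth, sd_bins = sd_bins),
         use.names = FALSE)
}
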