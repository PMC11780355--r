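# Single-unit tuning to whisker position: 33 ms binned tuning curves over 11
# angle bins, circular-shift shuffle nulls, cubic b-spline smoothing, k-means
# taxonomy, entropy/KL statistics, population-average tuning.

#' Single-unit tuning curves versus whisker position
#'
#' Spike counts and mean whisker angles are computed in time bins (default
#' 33 ms); the angle axis is discretized into 11 bins spanning the recording's
#' angle range and the firing rate (with SE across contributing time bins) is
#' averaged within each angle bin. When a bout table is supplied only time
#' bins inside whisking bouts contribute.
#'
#' @param spikes Tibble `unit_id`, `time` (s). Units with zero spikes yield an
#'   all-zero curve flagged `sparse`.
#' @param trace Tibble `time`, `angle`.
#' @param time_bin Time-bin width, s (default 0.033).
#' @param n_bins Number of angle bins (default 11).
#' @param angle_range Angle-axis limits, deg; recording min/max when `NULL`.
#' @param bouts Optional bout table restricting analysis to whisking periods.
#' @return Tibble `unit_id`, `bin`, `angle_lo`, `angle_hi`, `angle_mid`,
#'   `rate` (Hz), `rate_se`, `occupancy`, `n_timebins`, `sparse`.
#' @export
compute_tuning_curve <- function(spikes, trace, time_bin = 0.033, n_bins = 11,
                                 angle_range = NULL, bouts = NULL) {
  tb <- time_binned_activity(spikes, trace, time_bin, bouts)
  rng <- angle_range %||% range(trace$angle, na.rm = TRUE)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  tb$bin <- pmin(pmax(findInterval(tb$angle, edges, all.inside = TRUE), 1L), n_bins)
  total_tb <- length(unique(tb$tbin))

  units <- sort(unique(spikes$unit_id))
  grid <- tidyr::expand_grid(unit_id = units, bin = seq_len(n_bins))
  occ <- tb |>
    dplyr::distinct(.data$tbin, .data$bin) |>
    dplyr::count(.data$bin, name = "n_timebins") |>
    dplyr::mutate(occupancy = .data$n_timebins / total_tb)

  curves <- tb |>
    dplyr::group_by(.data$unit_id, .data$bin) |>
    dplyr::summarise(
      rate = mean(.data$count) / time_bin,
      rate_se = stats::sd(.data$count / time_bin) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  grid |>
    dplyr::left_join(curves, by = c("unit_id", "bin")) |>
    dplyr::left_join(occ, by = "bin") |>
    dplyr::mutate(
      rate = dplyr::coalesce(.data$rate, 0),
      rate_se = dplyr::coalesce(.data$rate_se, 0),
      occupancy = dplyr::coalesce(.data$occupancy, 0),
      n_timebins = dplyr::coalesce(.data$n_timebins, 0L),
      angle_lo = edges[.data$bin], angle_hi = edges[.data$bin + 1],
      angle_mid = (.data$angle_lo + .data$angle_hi) / 2
    ) |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::mutate(sparse = sum(.data$rate * .data$n_timebins) == 0) |>
    dplyr::ungroup() |>
    dplyr::select("unit_id", "bin", "angle_lo", "angle_hi", "angle_mid",
                  "rate", "rate_se", "occupancy", "n_timebins", "sparse")
}

# Long table of per-(unit, time-bin) spike counts paired with the bin's mean
# whisker angle. Every unit appears in every retained time bin (count 0 where
# silent).
time_binned_activity <- function(spikes, trace, time_bin, bouts = NULL) {
  t0 <- min(trace$time)
  n_tb <- floor((max(trace$time) - t0) / time_bin)
  if (n_tb < 1) rlang::abort("trace shorter than one time bin")
  bin_of <- function(t) pmin(pmax(floor((t - t0) / time_bin) + 1L, 1L), n_tb)

  ang <- tibble::tibble(tbin = bin_of(trace$time), angle = trace$angle) |>
    dplyr::filter(.data$tbin <= n_tb) |>
    dplyr::group_by(.data$tbin) |>
    dplyr::summarise(angle = mean(.data$angle), .groups = "drop")

  if (!is.null(bouts)) {
    centers <- t0 + (ang$tbin - 0.5) * time_bin
    ang <- ang[bouts_to_mask(bouts, centers), ]
  }

  units <- sort(unique(spikes$unit_id))
  counts <- spikes |>
    dplyr::mutate(tbin = bin_of(.data$time)) |>
    dplyr::count(.data$unit_id, .data$tbin, name = "count")
  tidyr::expand_grid(unit_id = units, tbin = ang$tbin) |>
    dplyr::left_join(counts, by = c("unit_id", "tbin")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    dplyr::left_join(ang, by = "tbin")
}

#' Shuffle null ensemble for tuning curves
#'
#' Breaks the spike-angle relationship while preserving each unit's spike-train
#' autocorrelation: the binned spike-count vector is circularly shifted by a
#' random offset (at least `min_shift` seconds, zero shift excluded) relative
#' to the angle vector and re-binned.
#'
#' @inheritParams compute_tuning_curve
#' @param n_shuffles Number of shuffles (>= 1).
#' @param min_shift Minimum circular shift, s.
#' @param seed Integer seed.
#' @return Tibble `shuffle`, `unit_id`, `bin`, `angle_mid`, `rate`.
#' @export
shuffle_tuning_null <- function(spikes, trace, n_shuffles = 100, min_shift = 1,
                                time_bin = 0.033, n_bins = 11,
                                angle_range = NULL, bouts = NULL, seed = 1L) {
  if (n_shuffles < 1) rlang::abort("n_shuffles must be >= 1")
  set.seed(seed)
  tb <- time_binned_activity(spikes, trace, time_bin, bouts)
  rng <- angle_range %||% range(trace$angle, na.rm = TRUE)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  tb$bin <- pmin(pmax(findInterval(tb$angle, edges, all.inside = TRUE), 1L), n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2

  wide <- tb |>
    dplyr::arrange(.data$unit_id, .data$tbin) |>
    tidyr::pivot_wider(id_cols = "tbin", names_from = "unit_id",
                       values_from = "count")
  bins_per_tb <- tb |> dplyr::distinct(.data$tbin, .data$bin) |>
    dplyr::arrange(.data$tbin)
  n_t <- nrow(wide)
  min_k <- max(1L, ceiling(min_shift / time_bin))
  if (n_t <= 2 * min_k) rlang::abort("trace too short for the minimum shift")

  purrr::map_dfr(seq_len(n_shuffles), function(sh) {
    k <- sample(min_k:(n_t - min_k), 1)
    idx <- ((seq_len(n_t) - 1 + k) %% n_t) + 1
    purrr::map_dfr(setdiff(names(wide), "tbin"), function(u) {
      cnt <- wide[[u]][idx]
      tibble::tibble(bin = bins_per_tb$bin, count = cnt) |>
        dplyr::group_by(.data$bin) |>
        dplyr::summarise(rate = mean(.data$count) / time_bin, .groups = "drop") |>
        tidyr::complete(bin = seq_len(n_bins), fill = list(rate = 0)) |>
        dplyr::mutate(shuffle = sh, unit_id = as.integer(u),
                      angle_mid = mids[.data$bin])
    })
  }) |>
    dplyr::select("shuffle", "unit_id", "bin", "angle_mid", "rate")
}

#' Smooth tuning curves with a 7-function cubic b-spline basis
#'
#' Least-squares fit of seven cubic b-spline basis functions over the angle-bin
#' index, denoising each curve while preserving its underlying structure. Units
#' with fewer than 7 occupied bins are fitted on the occupied bins with a small
#' ridge penalty and flagged.
#'
#' @param curves Tuning-curve tibble from [compute_tuning_curve()].
#' @param ridge Ridge penalty used only for under-determined fits.
#' @return Object of class `tuning_spline` with elements `curves` (adds
#'   `rate_smooth`), `coefficients` (tibble `unit_id`, `basis`, `value`; 7 per
#'   unit) and `flags` (`unit_id`, `ridged`).
#' @export
smooth_tuning <- function(curves, ridge = 1e-3) {
  n_bins <- max(curves$bin)
  B <- splines::bs(seq_len(n_bins), df = 7, intercept = TRUE)
  fits <- curves |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::group_map(function(df, key) {
      occ <- df$n_timebins > 0
      if (sum(occ) >= 7) {
        cf <- stats::lm.fit(B[df$bin, , drop = FALSE], df$rate)$coefficients
        ridged <- FALSE
      } else {
        Bo <- B[df$bin[occ], , drop = FALSE]
        cf <- solve(crossprod(Bo) + ridge * diag(7), crossprod(Bo, df$rate[occ]))
        ridged <- TRUE
      }
      cf[is.na(cf)] <- 0
      list(unit_id = key$unit_id, coef = as.numeric(cf),
           smooth = as.numeric(B %*% as.numeric(cf)), ridged = ridged)
    })
  sm <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(unit_id = f$unit_id, bin = seq_len(n_bins),
                   rate_smooth = f$smooth)
  })
  structure(list(
    curves = dplyr::left_join(curves, sm, by = c("unit_id", "bin")),
    coefficients = purrr::map_dfr(fits, function(f) {
      tibble::tibble(unit_id = f$unit_id, basis = 1:7, value = f$coef)
    }),
    flags = purrr::map_dfr(fits, function(f) {
      tibble::tibble(unit_id = f$unit_id, ridged = f$ridged)
    })
  ), class = "tuning_spline")
}

#' @export
tidy.tuning_spline <- function(x, ...) x$coefficients

#' k-means taxonomy of tuning-curve shapes
#'
#' Clusters units by their 7 b-spline coefficients (Euclidean k-means, default
#' k = 8, 10 restarts, seeded) and reports each cluster's mean raw tuning
#' curve.
#'
#' @param fits A `tuning_spline` object from [smooth_tuning()].
#' @param k Number of clusters (default 8).
#' @param nstart k-means restarts.
#' @param seed Integer seed.
#' @return Object of class `tuning_clusters`: `labels` (`unit_id`, `cluster`),
#'   `centers` (k x 7 matrix), `cluster_curves` (mean raw curve per cluster),
#'   `kmeans` (the underlying fit).
#' @export
cluster_tuning <- function(fits, k = 8, nstart = 10, seed = 1L) {
  stopifnot(inherits(fits, "tuning_spline"))
  X <- fits$coefficients |>
    tidyr::pivot_wider(names_from = "basis", values_from = "value",
                       names_prefix = "b") |>
    dplyr::arrange(.data$unit_id)
  M <- as.matrix(X[, -1])
  if (nrow(M) < k) rlang::abort(sprintf("need >= %d curves for k = %d", k, k))
  n_distinct <- nrow(unique(M))
  if (n_distinct < k) {
    rlang::inform(sprintf(
      "only %d distinct coefficient vectors; reducing k from %d", n_distinct, k))
    k <- n_distinct
  }
  set.seed(seed)
  km <- suppressWarnings(stats::kmeans(M, centers = k, nstart = nstart,
                                       iter.max = 50))
  labels <- tibble::tibble(unit_id = X$unit_id, cluster = km$cluster)
  cluster_curves <- fits$curves |>
    dplyr::left_join(labels, by = "unit_id") |>
    dplyr::group_by(.data$cluster, .data$bin) |>
    dplyr::summarise(angle_mid = mean(.data$angle_mid),
                     rate = mean(.data$rate), n_units = dplyr::n(),
                     .groups = "drop")
  structure(list(labels = labels, centers = km$centers,
                 cluster_curves = cluster_curves, kmeans = km),
            class = "tuning_clusters")
}

#' @export
tidy.tuning_clusters <- function(x, ...) x$labels

#' Shannon entropy of tuning curves
#'
#' Each unit's tuning curve is normalized to a probability mass function of
#' firing rate over whisker-position bins (empty/unoccupied bins excluded
#' before normalization) and its Shannon entropy computed in nats. Bounded by
#' `log(n_bins)`; all-zero curves give `NA` with a warning.
#'
#' @param curves Tuning-curve tibble from [compute_tuning_curve()].
#' @return Tibble `unit_id`, `entropy` (nats), `n_bins_used`.
#' @export
tuning_entropy <- function(curves) {
  out <- curves |>
    dplyr::filter(.data$n_timebins > 0, .data$rate > 0) |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(
      entropy = {
        p <- .data$rate / sum(.data$rate)
        -sum(p * log(p))
      },
      n_bins_used = dplyr::n(), .groups = "drop"
    )
  missing <- setdiff(unique(curves$unit_id), out$unit_id)
  if (length(missing) > 0) {
    rlang::warn(sprintf("entropy undefined for %d all-zero unit(s)", length(missing)))
    out <- dplyr::bind_rows(out, tibble::tibble(
      unit_id = missing, entropy = NA_real_, n_bins_used = 0L))
  }
  dplyr::arrange(out, .data$unit_id)
}

#' Kullback-Leibler divergence between paired tuning curves
#'
#' Computes `KL(pre || post)` per unit between the pre- and post-drug tuning
#' pmfs. Zeros are regularized by adding `eps` and renormalizing, so the
#' divergence is finite; `KL >= 0` with equality iff the regularized pmfs are
#' equal. `symmetrized = TRUE` returns the Jeffreys average
#' `(KL(p||q) + KL(q||p)) / 2`.
#'
#' @param pre,post Tuning-curve tibbles with identical units and binning.
#' @param eps Regularizer added to all bins before normalization.
#' @param symmetrized Return the symmetrized divergence?
#' @return Tibble `unit_id`, `kl` (nats).
#' @export
tuning_kl <- function(pre, post, eps = 1e-6, symmetrized = FALSE) {
  if (!identical(sort(unique(pre$unit_id)), sort(unique(post$unit_id))) ||
      max(pre$bin) != max(post$bin)) {
    rlang::abort("pre and post curves must share units and binning")
  }
  kl_dir <- function(p, q) sum(p * log(p / q))
  both <- dplyr::inner_join(
    dplyr::select(pre, "unit_id", "bin", rate_pre = "rate"),
    dplyr::select(post, "unit_id", "bin", rate_post = "rate"),
    by = c("unit_id", "bin"))
  both |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(kl = {
      p <- .data$rate_pre + eps; p <- p / sum(p)
      q <- .data$rate_post + eps; q <- q / sum(q)
      if (symmetrized) (kl_dir(p, q) + kl_dir(q, p)) / 2 else kl_dir(p, q)
    }, .groups = "drop")
}

#' Population-average tuning curve
#'
#' Unweighted mean (and SD) across units per angle bin, with the mean
#' occupancy overlaid and the whisker resting point marked (the angle bin of
#' maximum occupancy).
#'
#' @param curves Tuning-curve tibble from [compute_tuning_curve()].
#' @return Tibble `bin`, `angle_mid`, `rate_mean`, `rate_sd`, `occupancy`,
#'   `n_units`, `resting` (logical marker).
#' @export
population_tuning <- function(curves) {
  out <- curves |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(angle_mid = mean(.data$angle_mid),
                     rate_mean = mean(.data$rate),
                     rate_sd = stats::sd(.data$rate),
                     occupancy = mean(.data$occupancy),
                     n_units = dplyr::n(), .groups = "drop")
  out$rate_sd[is.na(out$rate_sd)] <- 0
  out$resting <- seq_len(nrow(out)) == which.max(out$occupancy)
  out
}

#' Exclude units too sparse during whisking
#'
#' Units whose activity is absent or too sparse during whisking periods carry
#' no usable tuning information; the default rule drops units firing fewer
#' than one spike per minute of whisking.
#'
#' @param spikes Tibble `unit_id`, `time`.
#' @param bouts Bout table defining whisking periods.
#' @param min_rate Minimum spikes per minute of whisking (default 1).
#' @return The spike tibble restricted to retained units, with attribute
#'   `excluded_units` listing the dropped unit ids.
#' @export
exclude_sparse_units <- function(spikes, bouts, min_rate = 1) {
  minutes <- sum(bouts$offset - bouts$onset) / 60
  if (minutes <= 0) rlang::abort("no whisking time in the bout table")
  in_bout <- bouts_to_mask(bouts, spikes$time)
  rates <- spikes[in_bout, ] |>
    dplyr::count(.data$unit_id) |>
    dplyr::mutate(per_min = .data$n / minutes)
  keep <- rates$unit_id[rates$per_min >= min_rate]
  dropped <- setdiff(unique(spikes$unit_id), keep)
  if (length(dropped) > 0) {
    rlang::inform(sprintf("excluding %d unit(s) sparse during whisking",
                          length(dropped)))
  }
  out <- dplyr::filter(spikes, .data$unit_id %in% keep)
  attr(out, "excluded_units") <- dropped
  out
}
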