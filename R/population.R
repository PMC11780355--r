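# Population analyses: bout-aligned PETHs, correlation-matrix PCA, loading
# statistics, neural-behavioral cross-correlation with lead/lag tests, and
# linear set-point decoding.

#' Peri-event time histograms aligned to whisking onset
#'
#' Trial-averaged firing rate of every unit on a common peri-onset grid
#' (default -2 to +3 s around bout onset, 3.3 ms bins), optionally smoothed
#' with a Gaussian window. Bouts whose window is truncated by the recording
#' edges are excluded.
#'
#' @param spikes Tibble `unit_id`, `time`.
#' @param bouts Bout table (`onset`, `offset`).
#' @param window Peri-onset window, s.
#' @param bin Bin width, s (default 0.0033).
#' @param smooth_sd_bins Gaussian smoothing SD, bins; 0 = none.
#' @param t_range Recording support, s; inferred from the spikes when `NULL`.
#' @return Tibble `unit_id`, `t` (bin centers), `rate` (Hz), with attributes
#'   `n_trials`, `bin`, `window`.
#' @export
compute_peth <- function(spikes, bouts, window = c(-2, 3), bin = 0.0033,
                         smooth_sd_bins = 0, t_range = NULL) {
  tr <- t_range %||% range(spikes$time)
  use <- bouts$onset + window[1] >= tr[1] & bouts$onset + window[2] <= tr[2]
  if (sum(use) < 1) rlang::abort("no usable bouts inside the recording")
  onsets <- bouts$onset[use]
  n_bins <- round(diff(window) / bin)
  centers <- window[1] + (seq_len(n_bins) - 0.5) * bin
  units <- sort(unique(spikes$unit_id))

  counts <- matrix(0, nrow = length(units), ncol = n_bins,
                   dimnames = list(units, NULL))
  for (on in onsets) {
    sel <- spikes$time >= on + window[1] & spikes$time < on + window[2]
    if (!any(sel)) next
    b <- floor((spikes$time[sel] - on - window[1]) / bin) + 1L
    b <- pmin(b, n_bins)
    tb <- table(factor(spikes$unit_id[sel], levels = units),
                factor(b, levels = seq_len(n_bins)))
    counts <- counts + unclass(tb)
  }
  rate <- counts / (length(onsets) * bin)
  if (smooth_sd_bins > 0) {
    rate <- t(apply(rate, 1, gaussian_smooth, sd_bins = smooth_sd_bins))
  }
  out <- tibble::tibble(
    unit_id = rep(as.integer(units), each = n_bins),
    t = rep(centers, length(units)),
    rate = as.numeric(t(rate))
  )
  attr(out, "n_trials") <- length(onsets)
  attr(out, "bin") <- bin
  attr(out, "window") <- window
  out
}

#' Correlation-matrix PCA of trial-averaged population activity
#'
#' Eigendecomposition of the inter-unit correlation matrix of trial-averaged
#' firing rates. Eigenvalues sum to the number of units; loadings
#' (eigenvectors, unit-norm) give each unit's contribution to a component and
#' are sign-fixed so the largest-magnitude loading is positive. Projections
#' are the loading-weighted sums of the standardized unit rates. Zero-variance
#' units are excluded with a message.
#'
#' @param peth PETH tibble from [compute_peth()].
#' @return Object of class `pop_pca`: `values` (eigenvalues, descending),
#'   `loadings` (tibble `unit_id`, `pc`, `loading`), `projections` (tibble
#'   `t`, `pc`, `value`), `var_explained` (tibble `pc`, `prop`, `cumulative`),
#'   `center`/`scale` (per-unit standardization), `units`, `dropped_units`.
#' @export
pca_population <- function(peth) {
  M <- peth |>
    tidyr::pivot_wider(id_cols = "t", names_from = "unit_id",
                       values_from = "rate") |>
    dplyr::arrange(.data$t)
  tgrid <- M$t
  X <- as.matrix(M[, -1])
  v <- apply(X, 2, stats::var)
  dropped <- as.integer(colnames(X)[v == 0])
  if (length(dropped) > 0) {
    rlang::inform(sprintf("excluding %d zero-variance unit(s) from PCA",
                          length(dropped)))
    X <- X[, v > 0, drop = FALSE]
  }
  if (ncol(X) < 3) rlang::abort("need >= 3 units with nonzero variance")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  Z <- scale(X, center = ctr, scale = scl)
  C <- stats::cor(X)
  e <- eigen(C, symmetric = TRUE)
  V <- apply(e$vectors, 2, function(w) w * sign(w[which.max(abs(w))]))
  P <- Z %*% V
  n_u <- ncol(X)
  ids <- as.integer(colnames(X))
  structure(list(
    values = e$values,
    loadings = tibble::tibble(
      unit_id = rep(ids, n_u),
      pc = rep(seq_len(n_u), each = n_u),
      loading = as.numeric(V)
    ),
    projections = tibble::tibble(
      t = rep(tgrid, n_u),
      pc = rep(seq_len(n_u), each = length(tgrid)),
      value = as.numeric(P)
    ),
    var_explained = tibble::tibble(
      pc = seq_len(n_u),
      prop = e$values / sum(e$values),
      cumulative = cumsum(e$values) / sum(e$values)
    ),
    center = stats::setNames(ctr, ids), scale = stats::setNames(scl, ids),
    units = ids, dropped_units = dropped
  ), class = "pop_pca")
}

#' @export
tidy.pop_pca <- function(x, ...) x$loadings

#' @export
glance.pop_pca <- function(x, ...) {
  tibble::tibble(
    n_units = length(x$units),
    n_dropped = length(x$dropped_units),
    var_pc1 = x$var_explained$prop[1],
    var_pc123 = x$var_explained$cumulative[min(3, nrow(x$var_explained))]
  )
}

#' Project single-trial activity onto population components
#'
#' Single-trial spike counts on the peri-onset grid are Gaussian-smoothed
#' (default SD 20 bins of 3.3 ms), centered by their own within-window mean,
#' scaled by the decomposition's per-unit SD, and projected onto the
#' loadings. Because projection, smoothing and centering are linear, the mean
#' over trials matches the projection of the trial-averaged PETH smoothed the
#' same way; a trial with no spikes projects to an identically zero
#' trajectory.
#'
#' @param spikes Tibble `unit_id`, `time`; must contain exactly the
#'   decomposition's unit set.
#' @param pca A `pop_pca` object.
#' @param bouts Bout table; one trial per usable bout.
#' @param window,bin Grid, as in [compute_peth()].
#' @param smooth_sd_bins Gaussian smoothing SD in bins (default 20).
#' @param pcs Components to return.
#' @param t_range Recording support, s.
#' @return Tibble `trial`, `t`, `pc`, `value`.
#' @export
project_single_trial <- function(spikes, pca, bouts, window = c(-2, 3),
                                 bin = 0.0033, smooth_sd_bins = 20, pcs = 1:3,
                                 t_range = NULL) {
  ids <- sort(unique(spikes$unit_id))
  if (!all(pca$units %in% ids)) {
    rlang::abort("spike data lacks units present in the decomposition")
  }
  tr <- t_range %||% range(spikes$time)
  use <- which(bouts$onset + window[1] >= tr[1] & bouts$onset + window[2] <= tr[2])
  if (length(use) < 1) rlang::abort("no usable bouts inside the recording")
  n_bins <- round(diff(window) / bin)
  centers <- window[1] + (seq_len(n_bins) - 0.5) * bin
  V <- pca$loadings |>
    dplyr::filter(.data$pc %in% pcs) |>
    tidyr::pivot_wider(id_cols = "unit_id", names_from = "pc",
                       values_from = "loading") |>
    dplyr::arrange(match(.data$unit_id, pca$units))
  Vm <- as.matrix(V[, -1])

  purrr::map_dfr(seq_along(use), function(j) {
    on <- bouts$onset[use[j]]
    sel <- spikes$time >= on + window[1] & spikes$time < on + window[2]
    b <- floor((spikes$time[sel] - on - window[1]) / bin) + 1L
    tb <- table(factor(spikes$unit_id[sel], levels = pca$units),
                factor(pmin(b, n_bins), levels = seq_len(n_bins)))
    rate <- unclass(tb) / bin
    if (smooth_sd_bins > 0) {
      rate <- t(apply(rate, 1, gaussian_smooth, sd_bins = smooth_sd_bins))
    }
    Z <- (rate - rowMeans(rate)) / pca$scale[as.character(pca$units)]
    P <- t(Z) %*% Vm
    tibble::tibble(trial = j,
                   t = rep(centers, length(pcs)),
                   pc = rep(pcs, each = n_bins),
                   value = as.numeric(P))
  })
}

#' Cross-correlation between population components and whisking
#'
#' Full normalized cross-correlogram between the whisker angle and each of the
#' first three component projections, on the shared peri-onset grid. Both
#' series are mean-subtracted; all correlograms are normalized by the absolute
#' maximum of the first component's, so the first component peaks at
#' magnitude 1. Positive lag means the neural signal leads behavior (its
#' features precede the whisker's by `peak_lag` seconds).
#'
#' @param projections Tibble `t`, `pc`, `value` (trial-averaged projections).
#' @param whisk Tibble `t`, `mean_angle` on the identical grid.
#' @param max_lag Largest lag examined, s.
#' @param pcs Components to correlate (default 1:3).
#' @return Object of class `pc_xcorr`: `xcorr` (tibble `pc`, `lag`, `value`)
#'   and `peaks` (tibble `pc`, `peak_lag`, `peak_value`; peak = largest
#'   `|value|`, earliest lag on ties).
#' @export
crosscorr_pc_whisking <- function(projections, whisk, max_lag = 1, pcs = 1:3) {
  tgrid <- sort(unique(projections$t))
  if (length(tgrid) != nrow(whisk) || max(abs(tgrid - whisk$t)) > 1e-9) {
    rlang::abort("projection and whisking grids must match")
  }
  w <- whisk$mean_angle - mean(whisk$mean_angle)
  if (stats::sd(w) == 0) rlang::abort("whisking input is constant; cross-correlation undefined")
  dt <- stats::median(diff(tgrid))
  L <- min(round(max_lag / dt), length(w) - 2)
  lags <- -L:L

  xc <- purrr::map_dfr(pcs, function(p) {
    x <- projections$value[projections$pc == p][order(projections$t[projections$pc == p])]
    x <- x - mean(x)
    if (stats::sd(x) == 0) {
      rlang::abort(sprintf("component %d is constant; cross-correlation undefined", p))
    }
    vals <- vapply(lags, function(k) {
      # positive k: neural (x) at t aligned with behavior (w) at t + k
      if (k >= 0) sum(x[1:(length(x) - k)] * w[(1 + k):length(w)])
      else sum(x[(1 - k):length(x)] * w[1:(length(w) + k)])
    }, numeric(1))
    tibble::tibble(pc = p, lag = lags * dt, value = vals)
  })
  norm <- max(abs(xc$value[xc$pc == pcs[1]]))
  xc$value <- xc$value / norm
  peaks <- xc |>
    dplyr::group_by(.data$pc) |>
    dplyr::slice(which.max(abs(.data$value))) |>
    dplyr::ungroup() |>
    dplyr::select("pc", peak_lag = "lag", peak_value = "value")
  structure(list(xcorr = xc, peaks = peaks), class = "pc_xcorr")
}

#' One-sample t test of cross-correlation peak lags
#'
#' Two-sided one-sample t test of the per-recording peak lags against zero
#' (lead/lag of a component relative to behavior across recordings).
#'
#' @param lags Numeric vector of peak lags, s (>= 3 values).
#' @return Tibble `mean`, `se`, `statistic`, `df`, `p.value`, `n`.
#' @export
peak_lag_test <- function(lags) {
  if (length(lags) < 3) rlang::abort("need >= 3 recordings")
  if (stats::sd(lags) == 0) {
    rlang::warn("zero variance in lags; t statistic undefined")
    return(tibble::tibble(mean = mean(lags), se = 0, statistic = NA_real_,
                          df = length(lags) - 1, p.value = NA_real_,
                          n = length(lags)))
  }
  tt <- stats::t.test(lags, mu = 0)
  tibble::tibble(mean = mean(lags), se = stats::sd(lags) / sqrt(length(lags)),
                 statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p.value = tt$p.value, n = length(lags))
}

#' Excess kurtosis of component loading distributions
#'
#' Fisher excess kurtosis (normal = 0) of the unit-loading distribution of
#' each component, pooled across recordings or per recording. An excess near
#' zero indicates contributions distributed across the population; large
#' positive values indicate components dominated by a few outlier units.
#'
#' @param loadings Tibble with columns `pc`, `loading` and optionally
#'   `recording`.
#' @param pcs Components summarized.
#' @param by `"pooled"` (default) or `"recording"`.
#' @return Tibble `pc` (and `recording` if per-recording), `excess_kurtosis`,
#'   `n`.
#' @export
loading_kurtosis <- function(loadings, pcs = 1:3, by = c("pooled", "recording")) {
  by <- match.arg(by)
  df <- dplyr::filter(loadings, .data$pc %in% pcs)
  grp <- if (by == "recording" && "recording" %in% names(df)) {
    dplyr::group_by(df, .data$recording, .data$pc)
  } else {
    dplyr::group_by(df, .data$pc)
  }
  grp |>
    dplyr::summarise(
      excess_kurtosis = {
        if (dplyr::n() < 4) NA_real_
        else e1071::kurtosis(.data$loading, type = 1)
      },
      n = dplyr::n(), .groups = "drop"
    )
}

#' Unexplained variance versus number of components
#'
#' Bookkeeping curve `1 - cumulative eigenvalue fraction`: monotone
#' non-increasing from just below 1 down to exactly 0 at the full rank.
#'
#' @param pca A `pop_pca` object.
#' @return Tibble `n_pcs`, `unexplained`.
#' @export
variance_explained_curve <- function(pca) {
  tibble::tibble(n_pcs = pca$var_explained$pc,
                 unexplained = 1 - pca$var_explained$cumulative)
}

#' Linear decoding of the whisking set point from population components
#'
#' Ordinary least squares of the set point on the first three component
#' trajectories, fit on training trials and evaluated on held-out trials; a
#' 94% highest-density band for the prediction is obtained by residual
#' bootstrap of the training fit.
#'
#' @param proj Tibble `trial`, `t`, `pc`, `value` from
#'   [project_single_trial()].
#' @param setpoint Tibble `trial`, `t`, `setpoint` on the same grid.
#' @param train_frac Fraction of trials used for fitting (>= 1 trial held
#'   out when possible).
#' @param n_boot Residual-bootstrap replicates.
#' @param prob Band mass (default 0.94).
#' @param pcs Components used as regressors.
#' @param seed Integer seed.
#' @return Object of class `setpoint_decoder`: `weights`, `predictions`
#'   (tibble `trial`, `t`, `actual`, `predicted`, `lo`, `hi`, `held_out`),
#'   `r2_train`, `r2_test`.
#' @export
decode_setpoint <- function(proj, setpoint, train_frac = 0.7, n_boot = 200,
                            prob = 0.94, pcs = 1:3, seed = 1L) {
  set.seed(seed)
  X <- proj |>
    dplyr::filter(.data$pc %in% pcs) |>
    tidyr::pivot_wider(id_cols = c("trial", "t"), names_from = "pc",
                       values_from = "value", names_prefix = "pc")
  df <- dplyr::inner_join(X, setpoint, by = c("trial", "t"))
  trials <- sort(unique(df$trial))
  n_train <- max(1, min(length(trials) - 1, round(train_frac * length(trials))))
  train_ids <- sort(sample(trials, n_train))
  df$held_out <- !(df$trial %in% train_ids)

  pcn <- paste0("pc", pcs)
  form <- stats::as.formula(paste("setpoint ~", paste(pcn, collapse = " + ")))
  Xtr <- as.matrix(df[!df$held_out, pcn])
  if (qr(cbind(1, Xtr))$rank < length(pcs) + 1) {
    rlang::warn("rank-deficient regressors; decoder weights not unique")
  }
  fit <- stats::lm(form, data = df[!df$held_out, ])
  pred <- stats::predict(fit, newdata = df)
  res <- stats::residuals(fit)

  Xall <- cbind(1, as.matrix(df[, pcn]))
  boot_pred <- matrix(NA_real_, nrow(df), n_boot)
  ytr <- df$setpoint[!df$held_out]
  Xtr1 <- cbind(1, Xtr)
  XtXi <- tryCatch(solve(crossprod(Xtr1)), error = function(e) NULL)
  for (b in seq_len(n_boot)) {
    yb <- stats::fitted(fit) + sample(res, length(res), replace = TRUE)
    cb <- if (is.null(XtXi)) stats::coef(stats::lm.fit(Xtr1, yb))
          else XtXi %*% crossprod(Xtr1, yb)
    boot_pred[, b] <- Xall %*% as.numeric(cb)
  }
  bands <- t(apply(boot_pred, 1, hdi, prob = prob))

  r2 <- function(sel) {
    y <- df$setpoint[sel]; yh <- pred[sel]
    1 - sum((y - yh)^2) / sum((y - mean(y))^2)
  }
  structure(list(
    weights = stats::coef(fit),
    predictions = tibble::tibble(trial = df$trial, t = df$t,
                                 actual = df$setpoint, predicted = pred,
                                 lo = bands[, 1], hi = bands[, 2],
                                 held_out = df$held_out),
    r2_train = r2(!df$held_out),
    r2_test = if (any(df$held_out)) r2(df$held_out) else NA_real_
  ), class = "setpoint_decoder")
}

#' @export
glance.setpoint_decoder <- function(x, ...) {
  tibble::tibble(r2_train = x$r2_train, r2_test = x$r2_test)
}
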