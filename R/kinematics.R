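# Whisker kinematics: landmark series -> azimuthal angle -> Hilbert
# phase/amplitude/set point -> whisking bouts -> bout-aligned averages.

#' Whisker azimuthal angle from tracked landmarks
#'
#' Angle between the first whisker segment (basal marker to second marker) and
#' the horizontal line through the basal marker, in degrees; increases
#' correspond to whisker protraction. Landmarks are in image coordinates with
#' y increasing downward, which the arctangent handles explicitly so that
#' protraction-positive holds. Frames with a tracking likelihood below
#' `likelihood_min` or with coincident basal/second markers are set to missing
#' and linearly interpolated up to `max_gap` consecutive frames (longer runs
#' stay `NA`), with a message.
#'
#' @param landmarks Tidy landmark tibble (`frame`, `time`, `bodypart`, `x`,
#'   `y`, `likelihood`), as from [simulate_landmarks()] or
#'   [read_dlc_landmarks()].
#' @param whisker Bodypart prefix selecting the analysis whisker (default
#'   `"C3"`, the most anterior). Markers are ordered by their numeric suffix;
#'   the basal marker is first.
#' @param likelihood_min Tracking-likelihood threshold.
#' @param max_gap Longest interpolated run, frames.
#' @return Tibble `time`, `angle` (deg).
#' @export
compute_whisker_angle <- function(landmarks, whisker = "C3",
                                  likelihood_min = 0.9, max_gap = 10) {
  lm <- dplyr::filter(landmarks, startsWith(.data$bodypart, whisker))
  if (nrow(lm) == 0) rlang::abort(sprintf("no landmarks for whisker '%s'", whisker))
  parts <- sort(unique(lm$bodypart))
  if (length(parts) < 2) rlang::abort("need at least 2 landmarks per frame")
  wide <- lm |>
    dplyr::filter(.data$bodypart %in% parts[1:2]) |>
    tidyr::pivot_wider(id_cols = c("frame", "time"),
                       names_from = "bodypart",
                       values_from = c("x", "y", "likelihood")) |>
    dplyr::arrange(.data$frame)
  x1 <- wide[[paste0("x_", parts[1])]]; y1 <- wide[[paste0("y_", parts[1])]]
  x2 <- wide[[paste0("x_", parts[2])]]; y2 <- wide[[paste0("y_", parts[2])]]
  l1 <- wide[[paste0("likelihood_", parts[1])]]
  l2 <- wide[[paste0("likelihood_", parts[2])]]

  dx <- x2 - x1
  dy <- y1 - y2                      # image y is down: protraction-positive
  bad <- (dx == 0 & dy == 0) | l1 < likelihood_min | l2 < likelihood_min |
    is.na(dx) | is.na(dy)
  angle <- atan2(dy, dx) * 180 / pi
  angle[bad] <- NA_real_
  if (any(bad)) {
    rlang::inform(sprintf(
      "%d frame(s) undefined (low likelihood or coincident markers); interpolating gaps <= %d frames",
      sum(bad), max_gap))
    angle <- interpolate_gaps(angle, max_gap)
  }
  tibble::tibble(time = wide$time, angle = angle)
}

# Linear interpolation of NA runs no longer than max_gap frames.
interpolate_gaps <- function(x, max_gap) {
  isna <- is.na(x)
  if (!any(isna) || all(isna)) return(x)
  filled <- stats::approx(which(!isna), x[!isna], xout = seq_along(x),
                          rule = 2)$y
  r <- rle(isna)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  for (i in which(r$values & r$lengths <= max_gap)) {
    x[starts[i]:ends[i]] <- filled[starts[i]:ends[i]]
  }
  x
}

#' Decompose a whisker-angle trace into phase, amplitude and set point
#'
#' The trace is band-passed (zero-phase Butterworth, default 4-25 Hz) and the
#' Hilbert analytic signal taken: its argument is the whisking phase and its
#' modulus the slowly varying whisking amplitude. The set point is the raw
#' trace low-passed below the whisking band (default 4 Hz). All filtering is
#' zero-phase, so the decomposition is free of causal lag.
#'
#' @param trace Tibble `time`, `angle`.
#' @param band Band-pass edges for the oscillatory component, Hz.
#' @param setpoint_cutoff Set-point low-pass cutoff, Hz.
#' @return Tibble `time`, `angle`, `phase` (rad, (-pi, pi]), `amplitude`
#'   (deg, >= 0), `setpoint` (deg).
#' @export
decompose_whisking <- function(trace, band = c(4, 25), setpoint_cutoff = 4) {
  fs <- infer_rate(trace$time)
  n <- nrow(trace)
  if (n < 10 * fs / band[1]) {
    rlang::abort("trace too short: need more than 10 filter time constants")
  }
  # odd-reflection padding suppresses filter edge transients, which the
  # global Hilbert kernel (~1/t) would otherwise smear into the interior
  np <- min(n - 1, ceiling(4 * fs / band[1]))
  x <- trace$angle
  xp <- c(2 * x[1] - x[(np + 1):2], x, 2 * x[n] - x[(n - 1):(n - np)])
  keep <- (np + 1):(np + n)
  # demean before band-passing: filtfilt starts from zero state, so a DC
  # offset would inject boundary transients
  osc <- bandpass_zero_phase(xp - mean(xp), fs, band)
  z <- analytic_signal(osc)[keep]
  tibble::tibble(
    time = trace$time,
    angle = trace$angle,
    phase = Arg(z),
    amplitude = Mod(z),
    setpoint = lowpass_zero_phase(xp, fs, setpoint_cutoff)[keep]
  )
}

#' Segment whisking bouts by thresholding the whisking amplitude
#'
#' The Hilbert amplitude is low-passed (default 6 Hz) and compared against a
#' 10 deg threshold (a Heaviside step discriminating whisking from rest).
#' Gaps shorter than `min_gap` are merged and bouts shorter than `min_bout`
#' dropped. An empty table is a valid result.
#'
#' @param kin Tibble from [decompose_whisking()] (needs `time`, `amplitude`).
#' @param threshold Amplitude threshold, deg (default 10).
#' @param amp_lowpass Amplitude low-pass cutoff before thresholding, Hz;
#'   `0` disables smoothing.
#' @param min_bout Minimum bout duration, s.
#' @param min_gap Gaps shorter than this are merged, s.
#' @return Tibble `onset`, `offset` (s), non-overlapping and sorted.
#' @export
detect_whisking_bouts <- function(kin, threshold = 10, amp_lowpass = 6,
                                  min_bout = 0.5, min_gap = 0.25) {
  fs <- infer_rate(kin$time)
  amp <- if (amp_lowpass > 0) lowpass_zero_phase(kin$amplitude, fs, amp_lowpass)
         else kin$amplitude
  mask <- amp > threshold
  bouts <- mask_to_bouts(mask, kin$time)
  merge_and_filter_bouts(bouts, min_bout, min_gap)
}

#' Convert a per-frame whisking mask to a bout table (and back)
#'
#' @param mask Logical vector.
#' @param time Frame times, s.
#' @return `mask_to_bouts`: tibble `onset`, `offset`. `bouts_to_mask`:
#'   logical vector over `time`.
#' @export
mask_to_bouts <- function(mask, time) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  on <- starts[r$values]; off <- ends[r$values]
  tibble::tibble(onset = time[on], offset = time[off])
}

#' @rdname mask_to_bouts
#' @param bouts Bout table (`onset`, `offset`).
#' @export
bouts_to_mask <- function(bouts, time) {
  mask <- rep(FALSE, length(time))
  for (i in seq_len(nrow(bouts))) {
    mask[time >= bouts$onset[i] & time <= bouts$offset[i]] <- TRUE
  }
  mask
}

# Merge bouts separated by < min_gap, then drop bouts < min_bout. Idempotent.
merge_and_filter_bouts <- function(bouts, min_bout = 0.5, min_gap = 0.25) {
  if (nrow(bouts) == 0) return(bouts)
  bouts <- dplyr::arrange(bouts, .data$onset)
  on <- bouts$onset[1]; off <- bouts$offset[1]
  ons <- c(); offs <- c()
  for (i in seq_len(nrow(bouts))[-1]) {
    if (bouts$onset[i] - off < min_gap) {
      off <- max(off, bouts$offset[i])
    } else {
      ons <- c(ons, on); offs <- c(offs, off)
      on <- bouts$onset[i]; off <- bouts$offset[i]
    }
  }
  ons <- c(ons, on); offs <- c(offs, off)
  keep <- (offs - ons) >= min_bout
  tibble::tibble(onset = ons[keep], offset = offs[keep])
}

#' Bout-onset-aligned average of the whisker angle
#'
#' Averages the angle trace across whisking bouts on a common peri-onset grid
#' (default -2 to +3 s around onset). Bouts whose window is truncated by the
#' recording edges are excluded.
#'
#' @param trace Tibble `time`, `angle`.
#' @param bouts Bout table (`onset`, `offset`).
#' @param window Peri-onset window, s.
#' @param grid Optional peri-onset sample grid, s (defaults to the trace's
#'   frame grid over `window`); pass a PETH bin-center grid to align with
#'   neural analyses.
#' @return Tibble `t`, `mean_angle`, `sd_angle`, `n`. Zero usable bouts gives
#'   a zero-row tibble with a warning.
#' @export
trial_average_whisking <- function(trace, bouts, window = c(-2, 3),
                                   grid = NULL) {
  fs <- infer_rate(trace$time)
  t0 <- min(trace$time); t1 <- max(trace$time)
  use <- bouts$onset + window[1] >= t0 & bouts$onset + window[2] <= t1
  if (!any(use)) {
    rlang::warn("no bout fits fully inside the recording; empty average")
    return(tibble::tibble(t = numeric(0), mean_angle = numeric(0),
                          sd_angle = numeric(0), n = integer(0)))
  }
  grid <- grid %||% seq(window[1], window[2], by = 1 / fs)
  mat <- vapply(bouts$onset[use], function(on) {
    stats::approx(trace$time, trace$angle, xout = on + grid)$y
  }, numeric(length(grid)))
  mat <- matrix(mat, nrow = length(grid))
  tibble::tibble(
    t = grid,
    mean_angle = rowMeans(mat),
    sd_angle = if (ncol(mat) > 1) apply(mat, 1, stats::sd) else rep(0, nrow(mat)),
    n = sum(use)
  )
}
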