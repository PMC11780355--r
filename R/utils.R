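# Shared numerical helpers: analytic signal, zero-phase filtering, Gaussian
# smoothing, highest-density intervals.

#' Analytic signal via the FFT
#'
#' Returns the complex analytic signal of a real series, whose argument is the
#' instantaneous phase and whose modulus is the instantaneous amplitude
#' (envelope). Frequency-domain construction: negative frequencies are zeroed,
#' positive frequencies doubled.
#'
#' @param x Numeric vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

# Zero-phase Butterworth band-pass (4th order by default).
bandpass_zero_phase <- function(x, fs, band, order = 4) {
  nyq <- fs / 2
  if (any(band <= 0) || any(band >= nyq) || band[1] >= band[2]) {
    rlang::abort(sprintf(
      "band [%g, %g] Hz must lie strictly inside (0, %g) Hz (Nyquist)",
      band[1], band[2], nyq
    ))
  }
  bf <- signal::butter(order, band / nyq, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# Zero-phase Butterworth low-pass.
lowpass_zero_phase <- function(x, fs, cutoff, order = 4) {
  nyq <- fs / 2
  if (cutoff <= 0 || cutoff >= nyq) {
    rlang::abort(sprintf("cutoff %g Hz must lie in (0, %g) Hz (Nyquist)", cutoff, nyq))
  }
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

#' Gaussian smoothing of a regularly sampled series
#'
#' Convolution with a truncated (4 SD) Gaussian kernel, renormalized at the
#' edges so that a constant input is returned unchanged.
#'
#' @param x Numeric vector.
#' @param sd_bins Kernel standard deviation in samples; `0` returns `x`.
#' @return Smoothed numeric vector of the same length.
#' @export
gaussian_smooth <- function(x, sd_bins) {
  if (sd_bins <= 0) return(x)
  n <- length(x)
  half <- max(1L, ceiling(4 * sd_bins))
  k <- stats::dnorm(seq(-half, half), sd = sd_bins)
  num <- stats::convolve(x, k, type = "open")[(half + 1):(half + n)]
  den <- stats::convolve(rep(1, n), k, type = "open")[(half + 1):(half + n)]
  num / den
}

#' Highest-density interval of posterior draws
#'
#' Shortest interval containing a given probability mass of a unimodal sample
#' (the convention used throughout for posterior summaries; default 94%).
#'
#' @param x Numeric vector of draws.
#' @param prob Probability mass, default `0.94`.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hdi <- function(x, prob = 0.94) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 2) return(c(lower = NA_real_, upper = NA_real_))
  m <- max(1L, floor(prob * n))
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[(m + 1):n] - x[1:(n - m)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m])
}

# Sample-rate inference from a time column (regular grid assumed).
infer_rate <- function(time) {
  dt <- diff(time)
  if (length(dt) < 1 || any(dt <= 0)) {
    rlang::abort("timestamps must be strictly increasing")
  }
  1 / stats::median(dt)
}

# Shift a vector by k samples (positive k advances: y[t] = x[t + k]),
# padding with the edge value.
shift_pad <- function(x, k) {
  n <- length(x)
  if (k == 0) return(x)
  if (k > 0) c(x[(k + 1):n], rep(x[n], min(k, n)))[1:n]
  else c(rep(x[1], min(-k, n)), x[1:(n + k)])[1:n]
}
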