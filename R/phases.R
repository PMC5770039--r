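#' @title Signal and phase tibbles
#' @description Signals and phases travel as tibbles with a `time` column
#' (seconds) and one numeric column per channel. The sampling interval is
#' inferred from `time` unless a sampling rate `fs` is supplied.
#' @name signal-tibbles
NULL

infer_dt <- function(data, fs = NULL) {
  if (!is.null(fs)) {
    if (fs <= 0) abort("`fs` must be positive.")
    return(1 / fs)
  }
  if (!"time" %in% names(data)) {
    abort("Supply `fs` or include a `time` column.")
  }
  dt <- median(diff(data$time))
  if (!is.finite(dt) || dt <= 0) abort("Non-increasing `time` column.")
  dt
}

channel_names <- function(data, channels = NULL) {
  cand <- setdiff(names(data), c("time", "trial"))
  if (is.null(channels)) return(cand)
  missing <- setdiff(channels, names(data))
  if (length(missing)) {
    abort(paste0("Unknown channel(s): ", paste(missing, collapse = ", ")))
  }
  channels
}

wrap_2pi <- function(x) x %% (2 * pi)

#' Unwrap a wrapped phase sequence
#'
#' Interprets jumps larger than pi between consecutive samples as wraps and
#' removes them, assuming sampling is fast relative to the oscillation.
#'
#' @param theta numeric vector of (possibly wrapped) angles (rad).
#' @return Unwrapped numeric vector.
#' @export
unwrap_phase <- function(theta) {
  d <- diff(theta)
  jumps <- round(d / (2 * pi))
  theta - c(0, cumsum(jumps)) * 2 * pi
}

## Analytic signal via FFT: zero negative frequencies, double positive ones.
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Protophase and amplitude from the analytic signal
#'
#' Forms the analytic signal `s(t) + i H[s](t)` of one mean-removed channel;
#' its argument is the protophase `theta` (wrapped to `[0, 2pi)`) and its
#' modulus the instantaneous amplitude. The protophase parameterises the
#' oscillation but does not grow uniformly in time; see
#' [protophase_to_phase()] for the correction to a proper phase.
#'
#' @param data signal tibble (see [signal-tibbles]).
#' @param channel channel (column) name; may be omitted for single-channel data.
#' @param fs sampling rate (Hz); inferred from `time` when absent.
#' @return Tibble with columns `time`, `theta` (rad, wrapped), `amplitude`.
#' @examples
#' t <- seq(0, 2, by = 1 / 500)
#' sig <- tibble::tibble(time = t, x = cos(2 * pi * 5 * t))
#' pp <- analytic_protophase(sig, "x")
#' @export
analytic_protophase <- function(data, channel = NULL, fs = NULL) {
  dt <- infer_dt(data, fs)
  channel <- channel %||% channel_names(data)[1]
  s <- data[[channel]]
  if (is.null(s)) abort(paste0("Unknown channel: ", channel))
  if (anyNA(s) || !all(is.finite(s))) abort("Signal contains NA or non-finite values.")
  if (length(s) < 4L) abort("Need at least 4 samples.")
  s <- s - mean(s)
  if (sd(s) == 0) abort("Constant signal: no oscillation to extract a phase from.")
  z <- analytic_signal(s)
  tibble(
    time = if ("time" %in% names(data)) data$time else (seq_along(s) - 1L) * dt,
    theta = wrap_2pi(Arg(z)),
    amplitude = Mod(z)
  )
}

#' Fourier-series estimate of the protophase density
#'
#' Estimates the stationary circular density `f(theta)` of a protophase track
#' from its empirical circular moments:
#' `f(theta) = (1/2pi) (1 + sum_k 2[ c_k cos(k theta) + s_k sin(k theta) ])`
#' with `c_k = mean(cos(k theta))`, `s_k = mean(sin(k theta))`, truncated at
#' `n_harmonics`. The density is evaluated on a uniform grid, clipped below at
#' `eps` and renormalised, which keeps the induced phase map strictly
#' increasing. `n_harmonics = 0` gives the uniform density exactly.
#'
#' @param theta protophase tibble from [analytic_protophase()], or a numeric
#'   vector of wrapped protophases (rad).
#' @param n_harmonics Fourier truncation order (default 10).
#' @param grid_n evaluation grid size (default 2048).
#' @param eps positivity floor for the density before renormalisation.
#' @return A `circular_density` object.
#' @export
estimate_density <- function(theta, n_harmonics = 10L, grid_n = 2048L,
                             eps = 1e-6) {
  th <- if (is.data.frame(theta)) theta$theta else theta
  if (length(th) == 0L) abort("Empty protophase input.")
  if (n_harmonics < 0L) abort("`n_harmonics` must be >= 0.")
  th <- wrap_2pi(th)
  k <- seq_len(n_harmonics)
  ck <- vapply(k, function(m) mean(cos(m * th)), numeric(1))
  sk <- vapply(k, function(m) mean(sin(m * th)), numeric(1))
  grid <- seq(0, 2 * pi, length.out = grid_n + 1L)
  f <- rep(1 / (2 * pi), grid_n + 1L)
  for (m in k) {
    f <- f + (ck[m] * cos(m * grid) + sk[m] * sin(m * grid)) / pi
  }
  f <- pmax(f, eps)
  ## trapezoid renormalisation on the closed grid
  w <- diff(grid)
  total <- sum((f[-1] + f[-length(f)]) / 2 * w)
  f <- f / total
  ## cumulative integral -> phase map, exact endpoints 0 and 2pi
  cumint <- c(0, cumsum((f[-1] + f[-length(f)]) / 2 * w))
  phi_grid <- 2 * pi * cumint / cumint[length(cumint)]
  structure(
    list(cos_coef = ck, sin_coef = sk, n_harmonics = n_harmonics,
         grid = grid, density = f, phi_grid = phi_grid, eps = eps),
    class = "circular_density"
  )
}

#' @export
print.circular_density <- function(x, ...) {
  cat(sprintf("<circular_density> %d harmonics on a %d-point grid\n",
              x$n_harmonics, length(x$grid) - 1L))
  invisible(x)
}

#' Transform a protophase series into a uniformly rotating phase
#'
#' Applies the protophase-to-phase map
#' `phi(theta) = 2 pi int_0^theta f(theta') dtheta'`
#' sample-wise, where `f` is the estimated circular density of the protophase.
#' The map is strictly increasing with `phi(0) = 0`, `phi(2 pi) = 2 pi`, so
#' every full turn of the protophase adds exactly `2 pi` to the phase; the
#' result is returned unwrapped. For a stationary oscillator the wrapped
#' corrected phase is uniformly distributed.
#'
#' @param theta protophase tibble from [analytic_protophase()] (or a numeric
#'   vector of protophases, possibly unwrapped).
#' @param density a `circular_density` from [estimate_density()]; computed
#'   from `theta` with defaults when omitted.
#' @param fs sampling rate (Hz), only used to synthesise a `time` column for
#'   vector input.
#' @return Tibble with columns `time` and `phi` (rad, unwrapped).
#' @export
protophase_to_phase <- function(theta, density = NULL, fs = NULL) {
  th_raw <- if (is.data.frame(theta)) theta$theta else theta
  density <- density %||% estimate_density(th_raw)
  if (!all(is.finite(density$density)) || any(density$density <= 0)) {
    abort("Non-normalizable density.")
  }
  th_u <- unwrap_phase(th_raw)
  turns <- floor(th_u / (2 * pi))
  frac <- th_u - 2 * pi * turns
  phi_frac <- approx(density$grid, density$phi_grid, xout = frac,
                     rule = 2)$y
  phi <- phi_frac + 2 * pi * turns
  tm <- if (is.data.frame(theta) && "time" %in% names(theta)) {
    theta$time
  } else {
    (seq_along(phi) - 1L) * if (is.null(fs)) 1 else 1 / fs
  }
  tibble(time = tm, phi = phi)
}

#' Shift the zero-phase reference of a phase series
#'
#' Adds a constant offset to an unwrapped phase track, e.g. to align the
#' Hilbert-derived zero phase with a model-defined reference point such as the
#' peak of an oscillator's voltage trace.
#'
#' @param phi phase tibble with a `phi` column, or a numeric vector.
#' @param offset_rad finite offset (rad).
#' @return Same shape as the input with the offset applied.
#' @export
shift_zero_phase <- function(phi, offset_rad) {
  if (!is.finite(offset_rad)) abort("`offset_rad` must be finite.")
  if (is.data.frame(phi)) {
    phi$phi <- phi$phi + offset_rad
    phi
  } else {
    phi + offset_rad
  }
}

#' Phase velocity by forward differencing
#'
#' `(phi(t_{tau+1}) - phi(t_tau)) / dt` on the unwrapped phase; the dependent
#' variable of the coupling regression. The result has one fewer sample than
#' the input.
#'
#' @param phi unwrapped phase vector, or a phase tibble with a `phi` column.
#' @param dt sampling interval (s); inferred from the tibble's `time` column.
#' @return Numeric vector of length `length(phi) - 1` (rad per unit time).
#' @export
phase_velocity <- function(phi, dt = NULL) {
  if (is.data.frame(phi)) {
    dt <- dt %||% infer_dt(phi)
    phi <- phi[[if ("phi" %in% names(phi)) "phi" else channel_names(phi)[1]]]
  }
  if (is.null(dt) || dt <= 0) abort("`dt` must be positive.")
  if (length(phi) < 2L) abort("Need at least 2 samples.")
  diff(phi) / dt
}

#' Zero-phase bandpass filtering and envelope extraction
#'
#' `mode = "band"` applies a 4th-order Butterworth bandpass forward and
#' backward (zero phase distortion). `mode = "envelope"` first takes the
#' modulus of the analytic signal (the instantaneous amplitude, e.g. a speech
#' envelope) and then bandpasses that envelope, isolating rhythmic components
#' of the amplitude such as syllabic (3-6 Hz) or prosodic (1-3 Hz) bands.
#'
#' @param data signal tibble.
#' @param low_hz,high_hz band edges (Hz), `0 < low < high < fs/2`.
#' @param mode `"band"` or `"envelope"`.
#' @param fs sampling rate (Hz); inferred from `time` when absent.
#' @param channels channels to process (default: all).
#' @param order Butterworth order (default 4).
#' @return Tibble of the same shape with filtered channels.
#' @export
bandpass_and_envelope <- function(data, low_hz, high_hz,
                                  mode = c("band", "envelope"),
                                  fs = NULL, channels = NULL, order = 4L) {
  mode <- match.arg(mode)
  dt <- infer_dt(data, fs)
  nyq <- 1 / (2 * dt)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    abort(sprintf("Invalid band: need 0 < low < high < fs/2 = %.4g Hz.", nyq))
  }
  channels <- channel_names(data, channels)
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  out <- data
  for (ch in channels) {
    x <- data[[ch]]
    if (mode == "envelope") {
      x <- Mod(analytic_signal(x - mean(x)))
    }
    out[[ch]] <- as.numeric(signal::filtfilt(bf, x - mean(x)))
  }
  out
}

#' Extract corrected phases from a multichannel signal
#'
#' Full preprocessing pipeline for each channel: remove the mean, form the
#' analytic signal, discard an edge margin (Hilbert end effects), estimate the
#' protophase density and apply the protophase-to-phase transformation. All
#' channels are trimmed by the same (largest) margin so they stay aligned.
#'
#' @param data signal tibble.
#' @param channels channels to convert (default: all non-`time` columns).
#' @param fs sampling rate (Hz); inferred from `time` when absent.
#' @param n_harmonics density truncation order (see [estimate_density()]).
#' @param margin_cycles edge margin, in periods of each channel's dominant
#'   frequency (default 1).
#' @return Tibble with `time` and one unwrapped-phase column per channel
#'   (same names as the input channels).
#' @export
extract_phase <- function(data, channels = NULL, fs = NULL,
                          n_harmonics = 10L, margin_cycles = 1) {
  dt <- infer_dt(data, fs)
  channels <- channel_names(data, channels)
  pps <- lapply(channels, function(ch) analytic_protophase(data, ch, fs = 1 / dt))
  ## margin: one dominant period per channel, applied uniformly
  margins <- vapply(pps, function(pp) {
    w <- mean(diff(unwrap_phase(pp$theta))) / dt
    ceiling(margin_cycles * 2 * pi / abs(w) / dt)
  }, numeric(1))
  m <- max(0L, min(max(margins), floor((nrow(data) - 4L) / 2)))
  keep <- seq.int(m + 1L, nrow(data) - m)
  out <- tibble(time = pps[[1]]$time[keep])
  for (k in seq_along(channels)) {
    th <- pps[[k]][keep, , drop = FALSE]
    dens <- estimate_density(th, n_harmonics = n_harmonics)
    out[[channels[k]]] <- protophase_to_phase(th, dens)$phi
  }
  if ("trial" %in% names(data)) out$trial <- data$trial[keep]
  out
}
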