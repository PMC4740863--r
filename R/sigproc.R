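#' Uniform frequency sweep
#'
#' The transceiver's stepped-frequency sweep. Defaults follow the acquisition
#' used throughout the package: `M = 284` samples covering 0.75-2.55 GHz.
#'
#' @param f_min,f_max band edges (Hz), `0 < f_min < f_max`.
#' @param n_samples number of frequency samples `M` (>= 2).
#' @return An object of class `frequency_sweep` with the uniform `frequencies`
#'   grid and spacing `df`.
#' @export
frequency_sweep <- function(f_min = 0.75e9, f_max = 2.55e9, n_samples = 284L) {
  if (f_min <= 0 || f_max <= f_min) stop("need 0 < f_min < f_max")
  if (n_samples < 2L) stop("need at least 2 frequency samples")
  f <- seq(f_min, f_max, length.out = n_samples)
  structure(
    list(f_min = f_min, f_max = f_max, n_samples = as.integer(n_samples),
         frequencies = f, df = f[2L] - f[1L]),
    class = "frequency_sweep"
  )
}

#' Fractional bandwidth of a sweep, percent
#'
#' `200 * (f_max - f_min) / (f_max + f_min)`; the default band gives 109%.
#'
#' @param sweep a [frequency_sweep()].
#' @return percent fractional bandwidth.
#' @export
fractional_bandwidth <- function(sweep = frequency_sweep()) {
  200 * (sweep$f_max - sweep$f_min) / (sweep$f_max + sweep$f_min)
}

#' Monostatic reflection-coefficient dataset
#'
#' Complex frequency-domain reflection coefficients `S_n(f_m)` measured by the
#' same antenna (monostatic) at each of `N` scan positions.
#'
#' @param s11 complex N x M matrix (positions x frequencies).
#' @param sweep a [frequency_sweep()] with `M = ncol(s11)` samples.
#' @param geometry a [scan_geometry()] with `N = nrow(s11)` positions.
#' @param snr_db optional declared signal-to-noise ratio (dB).
#' @return An object of class `reflection_dataset`.
#' @export
reflection_dataset <- function(s11, sweep, geometry, snr_db = NA_real_) {
  s11 <- as.matrix(s11)
  if (nrow(s11) != geometry$n_positions) {
    stop("s11 rows must match the number of scan positions")
  }
  if (ncol(s11) != sweep$n_samples) {
    stop("s11 columns must match the number of frequency samples")
  }
  if (any(!is.finite(Re(s11))) || any(!is.finite(Im(s11)))) {
    stop("s11 must be finite")
  }
  structure(
    list(s11 = s11, sweep = sweep, geometry = geometry, snr_db = snr_db),
    class = "reflection_dataset"
  )
}

#' @export
print.reflection_dataset <- function(x, ...) {
  cat(sprintf(
    "<reflection_dataset> %d positions x %d frequencies, %.2f-%.2f GHz%s\n",
    nrow(x$s11), ncol(x$s11), x$sweep$f_min / 1e9, x$sweep$f_max / 1e9,
    if (is.na(x$snr_db)) "" else sprintf(", SNR %g dB", x$snr_db)
  ))
  invisible(x)
}

#' Convert reflection coefficients to time-domain range profiles
#'
#' Per-position inverse discrete Fourier transform of `S_n` over the band,
#' zero-padded to `k_samples` points for smooth peak interpolation. The stored
#' samples are the complex analytic signal
#' \deqn{s_n(t_k) = \frac{1}{M} \sum_m S_n(f_m) e^{+j 2 \pi f_m t_k}}
#' whose real part is the physical waveform; an echo at round-trip delay
#' `tau0` produces `s(tau0)` equal to its (real) amplitude, which is what
#' makes the later coherent summation align across channels. Sample `k` maps
#' to time `k / (K df)` and to the one-way distance `c t / 2` from the antenna
#' phase center (positive distances from the point of excitation only).
#'
#' @param data a [reflection_dataset()].
#' @param k_samples output length `K >= M`; default 4x zero-padding.
#' @param window `"none"` or `"hann"` (applied across the band).
#' @return An object of class `time_signals`: complex `samples` (N x K),
#'   `time_axis` (s), `range_axis` (one-way mm), and back-references.
#' @export
to_time_domain <- function(data, k_samples = 4L * data$sweep$n_samples,
                           window = c("none", "hann")) {
  window <- match.arg(window)
  m <- data$sweep$n_samples
  if (k_samples < m) stop("k_samples must be at least the number of frequency samples")
  k <- as.integer(k_samples)
  s <- data$s11
  w <- if (window == "hann") {
    0.5 - 0.5 * cos(2 * pi * (seq_len(m) - 1L) / (m - 1L))
  } else rep(1, m)
  sw <- sweep(s, 2L, w, `*`)
  t_axis <- (seq_len(k) - 1L) / (k * data$sweep$df)
  carrier <- exp(2i * pi * data$sweep$f_min * t_axis)
  n <- nrow(s)
  out <- matrix(0i, n, k)
  for (i in seq_len(n)) {
    padded <- c(sw[i, ], rep(0i, k - m))
    base <- stats::fft(padded, inverse = TRUE) / m
    out[i, ] <- base * carrier
  }
  structure(
    list(
      samples = out, time_axis = t_axis,
      range_axis = C0 * t_axis / 2 * 1e3,
      sweep = data$sweep, geometry = data$geometry,
      window = window, k_samples = k, zero_flags = rep(FALSE, n),
      normalized = FALSE
    ),
    class = "time_signals"
  )
}

#' Forward transform of time signals back to the band bins
#'
#' Exact inverse of [to_time_domain()] (window `"none"`): recovers the M
#' in-band reflection-coefficient samples.
#'
#' @param signals a `time_signals` object produced with `window = "none"`.
#' @return complex N x M matrix.
#' @export
from_time_domain <- function(signals) {
  k <- signals$k_samples
  m <- signals$sweep$n_samples
  carrier <- exp(-2i * pi * signals$sweep$f_min * signals$time_axis)
  t(apply(signals$samples, 1L, function(row) {
    stats::fft(row * carrier)[seq_len(m)] * m / k
  }))
}

#' Integer-lag circular shift of a vector
#' @noRd
shift_signal <- function(x, lag) {
  k <- length(x)
  lag <- ((lag %% k) + k) %% k
  if (lag == 0L) x else c(x[(k - lag + 1L):k], x[1L:(k - lag)])
}

#' Best integer alignment lag of y onto x (bounded cross-correlation)
#' @noRd
best_lag <- function(x, y, max_lag) {
  lags <- -max_lag:max_lag
  score <- vapply(lags, function(l) Mod(sum(x * Conj(shift_signal(y, l)))),
                  numeric(1L))
  lags[which.max(score)]
}

#' Adjacent average subtraction (skin-clutter removal)
#'
#' The dominant air-skin interface echo is nearly identical at adjacent,
#' equidistant scan positions. For each position `n` the average of its two
#' ring neighbors' signals is subtracted, leaving the scattered signal
#' `s_hat_n`. With `align = TRUE` the Woody variant is used: each neighbor is
#' first shifted by the integer lag (bounded to 5% of the record length) that
#' maximizes its cross-correlation with the signal at position `n`, which
#' reduces the residual when the skin echo drifts between positions.
#'
#' @param signals a `time_signals` object with `N >= 3` positions.
#' @param align use Woody alignment before averaging.
#' @return A `time_signals` object of scattered signals.
#' @export
adjacent_average_subtract <- function(signals, align = FALSE) {
  s <- signals$samples
  n <- nrow(s)
  if (n < 3L) stop("adjacent average subtraction needs at least 3 positions")
  k <- ncol(s)
  max_lag <- max(1L, floor(0.05 * k))
  out <- s
  for (i in seq_len(n)) {
    prev <- s[if (i == 1L) n else i - 1L, ]
    nxt <- s[if (i == n) 1L else i + 1L, ]
    if (align) {
      prev <- shift_signal(prev, best_lag(s[i, ], prev, max_lag))
      nxt <- shift_signal(nxt, best_lag(s[i, ], nxt, max_lag))
    }
    out[i, ] <- s[i, ] - (prev + nxt) / 2
  }
  signals$samples <- out
  signals
}

#' Normalize scattered signals to unit peak amplitude
#'
#' Compensates the antenna gain variation by scaling each position's scattered
#' signal to unit peak absolute amplitude. All-zero positions are left
#' unchanged and flagged in `zero_flags`.
#'
#' @param signals a `time_signals` object.
#' @return A `time_signals` object with per-position peaks of 1 and attribute
#'   `peaks` holding the original peak amplitudes.
#' @export
normalize_gain <- function(signals) {
  peaks <- apply(Mod(signals$samples), 1L, max)
  zero <- peaks == 0
  scale <- ifelse(zero, 1, 1 / peaks)
  signals$samples <- signals$samples * scale
  signals$zero_flags <- zero
  signals$normalized <- TRUE
  attr(signals, "peaks") <- peaks
  signals
}

#' Excitation pulse specification
#'
#' Gaussian-modulated sinusoid used as the system excitation. Defaults place
#' the spectral peak at 1.6 GHz with a 1.7 ns total envelope duration so the
#' -10 dB spectral extent covers the 0.75-2.55 GHz operating band. The width
#' `tau` is the full envelope duration; the Gaussian envelope sigma is
#' `tau / 7` (the envelope is below 0.3% of peak outside `tau`).
#'
#' @param f_c central frequency (Hz).
#' @param tau pulse width (s).
#' @return An object of class `pulse_spec`.
#' @export
pulse_spec <- function(f_c = 1.6e9, tau = 1.7e-9) {
  if (f_c <= 0 || tau <= 0) stop("f_c and tau must be positive")
  structure(list(f_c = f_c, tau = tau), class = "pulse_spec")
}

#' Evaluate the Gaussian-modulated excitation pulse on a time grid
#'
#' @param spec a [pulse_spec()].
#' @param t uniform time grid (s) spanning at least `6 * tau`.
#' @return numeric amplitude series with peak envelope at the grid center.
#' @export
gaussian_pulse <- function(spec, t) {
  if (length(t) < 2L) stop("time grid too short")
  dt <- diff(t)
  if (max(dt) - min(dt) > 1e-15 + 1e-9 * max(abs(dt))) {
    stop("time grid must be uniform")
  }
  if ((t[length(t)] - t[1L]) < 6 * spec$tau) {
    stop("time grid must span at least 6 pulse widths")
  }
  t0 <- (t[1L] + t[length(t)]) / 2
  sigma <- spec$tau / 7
  exp(-0.5 * ((t - t0) / sigma)^2) * cos(2 * pi * spec$f_c * (t - t0))
}

#' Closed-form positive-frequency spectrum envelope of the pulse
#'
#' Gaussian spectral envelope `exp(-2 pi^2 sigma^2 (f - f_c)^2)` (unit peak),
#' used by the synthetic forward model to shape echo spectra.
#'
#' @param spec a [pulse_spec()].
#' @param f frequencies (Hz).
#' @return numeric envelope values in (0, 1].
#' @export
pulse_spectrum <- function(spec, f) {
  sigma <- spec$tau / 7
  exp(-2 * pi^2 * sigma^2 * (f - spec$f_c)^2)
}

#' Noise configuration
#'
#' @param snr_db target dataset-wide signal-to-noise ratio (dB); `Inf` means
#'   no noise.
#' @param seed integer seed; a fixed seed gives bit-reproducible draws.
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(snr_db, seed = 1L) {
  structure(list(snr_db = snr_db, seed = as.integer(seed)),
            class = "noise_config")
}

#' Add complex white Gaussian noise at a target SNR
#'
#' The noise power is scaled against the total dataset signal power (one SNR
#' per experiment, not per position). Reproducible under a fixed seed; the
#' caller's random-number state is restored afterwards.
#'
#' @param data a [reflection_dataset()].
#' @param cfg a [noise_config()].
#' @return A [reflection_dataset()] with `snr_db` recorded.
#' @export
add_noise <- function(data, cfg) {
  if (is.infinite(cfg$snr_db)) {
    data$snr_db <- Inf
    return(data)
  }
  s <- data$s11
  sig_p <- mean(Mod(s)^2)
  noise_p <- sig_p * 10^(-cfg$snr_db / 10)
  sd_comp <- sqrt(noise_p / 2)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)
  noise <- matrix(
    complex(real = stats::rnorm(length(s), sd = sd_comp),
            imaginary = stats::rnorm(length(s), sd = sd_comp)),
    nrow(s), ncol(s)
  )
  reflection_dataset(s + noise, data$sweep, data$geometry, snr_db = cfg$snr_db)
}

#' Export time signals to CSV
#'
#' Long format: `position, k, time_s, range_mm, amplitude` (real part) for
#' plotting range profiles.
#'
#' @param signals a `time_signals` object.
#' @param path CSV file path.
#' @export
write_time_signals <- function(signals, path) {
  n <- nrow(signals$samples)
  k <- ncol(signals$samples)
  df <- data.frame(
    position = rep(seq_len(n), each = k),
    k = rep(seq_len(k) - 1L, times = n),
    time_s = rep(signals$time_axis, times = n),
    range_mm = rep(signals$range_axis, times = n),
    amplitude = as.vector(t(Re(signals$samples)))
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
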