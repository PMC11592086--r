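# Synthetic sEMG generation and conversion to muscle activation.
#
# The generator emulates an 8-channel armband sampling at 200 Hz: each
# channel is zero-mean band-limited Gaussian noise (the usual surrogate
# for the sEMG interference pattern) whose amplitude is modulated by a
# piecewise-linear contraction envelope, plus a small additive noise
# floor. Downstream, the rectified and low-pass filtered signal alpha(t)
# is mapped to the muscle activation r(t) through an exponential shape
# nonlinearity.

#' Activation profile (contraction envelope)
#'
#' A piecewise-linear envelope in `[0, 1]` describing how strongly the
#' muscle is driven over time. The envelope multiplies the amplitude of
#' the synthetic sEMG interference pattern, so the RMS of the generated
#' signal is proportional to the envelope level.
#'
#' @param times breakpoint times in seconds, non-decreasing; the last
#'   breakpoint sets the recording duration.
#' @param levels envelope levels in `[0, 1]`, one per breakpoint.
#' @return an object of class `activation_profile`.
#' @examples
#' prof <- activation_profile(c(0, 0.5, 2), c(0, 0.3, 0.3))
#' @export
activation_profile <- function(times, levels) {
  if (length(times) == 0 || length(times) != length(levels))
    stop("profile needs matching, non-empty times and levels", call. = FALSE)
  if (is.unsorted(times)) stop("profile times must be non-decreasing", call. = FALSE)
  if (any(levels < 0 | levels > 1)) stop("profile levels must lie in [0, 1]", call. = FALSE)
  structure(list(times = as.numeric(times), levels = as.numeric(levels)),
            class = "activation_profile")
}

#' Evaluate an activation profile
#'
#' @param profile an [activation_profile()].
#' @param t times at which to evaluate (seconds).
#' @return envelope levels in `[0, 1]`.
#' @export
profile_envelope <- function(profile, t) {
  stopifnot(inherits(profile, "activation_profile"))
  if (length(profile$times) == 1) return(rep(profile$levels, length(t)))
  stats::approx(profile$times, profile$levels, xout = t, rule = 2)$y
}

# Band-limited unit-RMS Gaussian noise: white noise, zero-phase band-pass,
# rescaled to RMS 1 over the record.
band_noise <- function(n, rate, band) {
  x <- stats::rnorm(n)
  ny <- rate / 2
  w <- c(max(band[1], 1e-3) / ny, min(band[2], 0.999 * ny) / ny)
  bf <- signal::butter(4, w, type = "pass")
  y <- signal::filtfilt(bf, x)
  y <- y - mean(y)
  y / sqrt(mean(y^2))
}

#' Generate seeded synthetic multichannel sEMG
#'
#' Each channel is independent band-limited zero-mean Gaussian noise
#' (default passband 20-95 Hz) normalized to unit RMS, multiplied by the
#' interpolated contraction envelope, plus an additive band-limited noise
#' floor of RMS `noise_floor`. Identical `(profile, seed)` pairs give
#' bit-identical recordings.
#'
#' @param profile an [activation_profile()]; its last breakpoint sets the
#'   duration.
#' @param n_channels number of electrode channels (>= 1), default 8.
#' @param rate sampling rate in Hz, default 200.
#' @param seed integer RNG seed.
#' @param band passband of the interference-pattern noise in Hz.
#' @param noise_floor RMS of the additive baseline noise, in the same
#'   arbitrary amplitude units as the envelope-modulated signal.
#' @return an object of class `emg_recording`: list with `time` (s),
#'   `channels` (samples x channels matrix) and `rate` (Hz).
#' @examples
#' emg <- generate_synthetic_emg(activation_profile(c(0, 1), c(0.2, 0.2)),
#'                               n_channels = 2, seed = 1)
#' @export
generate_synthetic_emg <- function(profile, n_channels = 8, rate = 200,
                                   seed = 1, band = c(20, 95),
                                   noise_floor = 0.01) {
  stopifnot(inherits(profile, "activation_profile"))
  if (n_channels < 1) stop("n_channels must be >= 1", call. = FALSE)
  if (rate <= 0) stop("rate must be positive", call. = FALSE)
  duration <- max(profile$times)
  if (duration <= 0) stop("profile duration must be positive", call. = FALSE)
  time <- seq(0, duration, by = 1 / rate)
  env <- profile_envelope(profile, time)
  channels <- with_seed(seed, {
    vapply(seq_len(n_channels), function(ch) {
      env * band_noise(length(time), rate, band) +
        noise_floor * band_noise(length(time), rate, band)
    }, numeric(length(time)))
  })
  structure(list(time = time, channels = channels, rate = rate),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("sEMG recording: %d channels, %d samples at %g Hz (%.2f s)\n",
              ncol(x$channels), length(x$time), x$rate,
              max(x$time)))
  invisible(x)
}

validate_emg <- function(emg) {
  stopifnot(inherits(emg, "emg_recording"))
  if (!is_uniform_grid(emg$time))
    stop("EMG time grid must be uniform and strictly increasing", call. = FALSE)
  if (abs(mean(diff(emg$time)) - 1 / emg$rate) > 1e-6 / emg$rate)
    stop("EMG time step inconsistent with declared rate", call. = FALSE)
  if (!all(is.finite(emg$channels)))
    stop("EMG contains non-finite values", call. = FALSE)
  invisible(emg)
}

#' Normalized activation alpha(t) from an sEMG recording
#'
#' Channels are full-wave rectified, averaged, low-pass filtered with a
#' zero-phase 2nd-order Butterworth filter, divided by the maximum
#' voluntary contraction level and clipped to `[0, 1]`.
#'
#' @param emg an `emg_recording`.
#' @param cutoff low-pass cutoff in Hz (0 < cutoff < rate/2), default 2.
#' @param mvc_level rectified-amplitude level corresponding to maximum
#'   voluntary contraction; default 0.8 (the rectified mean of a
#'   unit-RMS Gaussian channel at full envelope is `sqrt(2/pi) ~ 0.80`).
#' @return data.frame of class `activation_trace` with columns `time`
#'   and `alpha`.
#' @export
compute_alpha <- function(emg, cutoff = 2, mvc_level = 0.8) {
  validate_emg(emg)
  if (cutoff <= 0 || cutoff >= emg$rate / 2)
    stop("cutoff must satisfy 0 < cutoff < rate/2", call. = FALSE)
  if (mvc_level <= 0) stop("mvc_level must be positive", call. = FALSE)
  rect <- rowMeans(abs(emg$channels))
  bf <- signal::butter(2, cutoff / (emg$rate / 2), type = "low")
  filt <- signal::filtfilt(bf, rect)
  alpha <- clamp(filt / mvc_level, 0, 1)
  structure(data.frame(time = emg$time, alpha = alpha),
            class = c("activation_trace", "data.frame"))
}

#' Muscle activation nonlinearity r(alpha)
#'
#' Maps the filtered, normalized sEMG level `alpha` to the muscle
#' activation `r = (exp(gamma * alpha) - 1) / (exp(gamma) - 1)`. The
#' endpoints map exactly (`r(0) = 0`, `r(1) = 1`); the curve is convex
#' for `gamma > 0` and concave for `gamma < 0`. At `gamma = 0` the
#' analytic limit `r = alpha` is used.
#'
#' @param alpha activation level(s) in `[0, 1]`.
#' @param gamma dimensionless shape constant; default -3.
#' @return activation value(s) in `[0, 1]`.
#' @examples
#' activation(0.5, gamma = 2)  # = 1 / (e + 1)
#' @export
activation <- function(alpha, gamma = -3) {
  if (any(alpha < 0 | alpha > 1)) stop("alpha must lie in [0, 1]", call. = FALSE)
  if (gamma == 0) return(alpha)
  expm1(gamma * alpha) / expm1(gamma)
}

#' Full activation trace: alpha and r on the EMG time grid
#'
#' Convenience wrapper running [compute_alpha()] then [activation()].
#'
#' @inheritParams compute_alpha
#' @param gamma shape constant passed to [activation()].
#' @return data.frame of class `activation_trace` with columns `time`,
#'   `alpha`, `r`; `gamma` is stored as an attribute.
#' @export
activation_trace <- function(emg, cutoff = 2, mvc_level = 0.8, gamma = -3) {
  tr <- compute_alpha(emg, cutoff, mvc_level)
  tr$r <- activation(tr$alpha, gamma)
  attr(tr, "gamma") <- gamma
  tr
}

#' Write / read an EMG recording as CSV
#'
#' Header `time,ch1,...,chN`; times in seconds on a uniform grid. Values
#' round-trip bit-exactly (written with full precision).
#'
#' @param emg an `emg_recording`.
#' @param path file path.
#' @export
write_emg_csv <- function(emg, path) {
  validate_emg(emg)
  df <- data.frame(time = emg$time, emg$channels)
  names(df) <- c("time", paste0("ch", seq_len(ncol(emg$channels))))
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_emg_csv
#' @param rate sampling rate in Hz; if `NULL`, inferred from the time
#'   column.
#' @export
read_emg_csv <- function(path, rate = NULL) {
  df <- utils::read.csv(path)
  if (names(df)[1] != "time") stop("first CSV column must be `time`", call. = FALSE)
  time <- df$time
  if (!is_uniform_grid(time))
    stop("non-uniform time grid in EMG CSV", call. = FALSE)
  if (is.null(rate)) rate <- 1 / mean(diff(time))
  structure(list(time = time,
                 channels = as.matrix(df[, -1, drop = FALSE]),
                 rate = rate),
            class = "emg_recording")
}
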