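#' Construct a raw EMG trial
#'
#' Holds multi-channel raw EMG samples with their sampling rate, muscle
#' names, optional direction label, optional per-muscle maximum voluntary
#' contraction (MVC) amplitudes and the session mode. The decoder itself
#' consumes non-normalized linear envelopes; MVC values are used only to
#' normalize integrated EMG in the evaluation layer.
#'
#' @param samples numeric matrix, channels x time.
#' @param fs_raw sampling rate in Hz (default 1000).
#' @param muscle_names ordered channel labels; defaults to the six recorded
#'   upper-limb muscles.
#' @param direction compass label (see [DIRECTIONS]) or NA.
#' @param mvc named per-muscle MVC amplitudes (same units as `samples`) or NULL.
#' @param mode "transparent" or "assistive".
#' @return an object of class `emg_trial`.
#' @export
emg_trial <- function(samples, fs_raw = 1000,
                      muscle_names = default_muscles(),
                      direction = NA_character_,
                      mvc = NULL,
                      mode = c("transparent", "assistive")) {
  mode <- match.arg(mode)
  samples <- as.matrix(samples)
  if (!all(is.finite(samples))) stop("non-finite values in EMG samples")
  if (fs_raw <= 0) stop("fs_raw must be positive")
  if (nrow(samples) != length(muscle_names))
    stop("samples has ", nrow(samples), " channels but ", length(muscle_names),
         " muscle names were given")
  if (!is.null(mvc)) {
    mvc <- mvc[muscle_names]
    if (anyNA(mvc) || any(mvc <= 0)) stop("mvc must be strictly positive for every muscle")
  }
  rownames(samples) <- muscle_names
  structure(list(samples = samples, fs_raw = fs_raw, muscle_names = muscle_names,
                 direction = direction, mvc = mvc, mode = mode),
            class = "emg_trial")
}

#' Default recorded muscle set
#' @return character vector of the six muscle labels.
#' @export
default_muscles <- function() {
  c("biceps_brachii", "triceps_brachii", "anterior_deltoid",
    "medial_deltoid", "posterior_deltoid", "upper_trapezius")
}

#' Construct an envelope series
#'
#' The universal signal currency: a non-negative channels x time matrix of
#' linear envelopes with its sampling rate.
#'
#' @param values non-negative numeric matrix, channels x time.
#' @param fs sampling rate in Hz.
#' @param muscle_names optional channel labels.
#' @return an object of class `envelope_series`.
#' @export
envelope_series <- function(values, fs, muscle_names = rownames(values)) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("envelope values must be non-negative")
  if (!is.null(muscle_names)) rownames(values) <- muscle_names
  structure(list(values = values, fs = fs, muscle_names = muscle_names),
            class = "envelope_series")
}

#' @export
print.envelope_series <- function(x, ...) {
  cat(sprintf("<envelope_series> %d channels x %d samples @ %g Hz\n",
              nrow(x$values), ncol(x$values), x$fs))
  invisible(x)
}

# Biquad notch (RBJ cookbook): unit gain away from f0, zero at f0.
design_notch <- function(f0, fs, Q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  list(b = b, a = a)
}

#' Default filter-chain and onset configuration
#'
#' @return a list with components `filters` (band-pass edges, notch frequency
#'   and quality factor, low-pass cutoff), `onset` (adaptive-threshold gain
#'   and window length) and `rates` (raw and control-loop sampling rates).
#' @export
default_config <- function() {
  list(
    filters = list(bandpass_hz = c(20, 400), notch_hz = 50, notch_q = 30,
                   lowpass_hz = 4),
    onset = list(gain_h = 10, window_ms = 150),
    rates = list(raw_hz = 1000, control_hz = 100)
  )
}

#' Compute causal linear envelopes from raw EMG
#'
#' Applies, in order and all causally (single-pass IIR filtering, as the
#' online system must): a 4th-order Butterworth band-pass, a 2nd-order notch
#' at the mains frequency, full-wave rectification, and a 2nd-order
#' Butterworth low-pass. Tiny negative overshoot from the final low-pass is
#' clamped to zero so the envelope invariant holds.
#'
#' @param trial an [emg_trial()].
#' @param config configuration list as from [default_config()].
#' @return an `envelope_series` at the raw sampling rate.
#' @export
compute_envelope <- function(trial, config = default_config()) {
  stopifnot(inherits(trial, "emg_trial"))
  fs <- trial$fs_raw
  f <- config$filters
  nyq <- fs / 2
  if (max(f$bandpass_hz) >= nyq || f$notch_hz >= nyq || f$lowpass_hz >= nyq)
    stop("filter band edge at or above Nyquist (", nyq, " Hz)")
  if (ncol(trial$samples) < 0.5 * fs)
    stop("trial shorter than filter warm-up (0.5 s)")

  bp <- signal::butter(2, f$bandpass_hz / nyq, type = "pass")   # order 2n = 4
  nt <- design_notch(f$notch_hz, fs, f$notch_q)
  lp <- signal::butter(2, f$lowpass_hz / nyq, type = "low")

  env <- t(apply(trial$samples, 1, function(x) {
    y <- signal::filter(bp$b, bp$a, x)
    y <- signal::filter(nt$b, nt$a, y)
    y <- abs(y)
    y <- signal::filter(lp$b, lp$a, y)
    pmax(as.numeric(y), 0)
  }))
  envelope_series(env, fs, trial$muscle_names)
}

#' Decimate an envelope series to the control rate
#'
#' Keeps every k-th sample, k = fs / target_fs. The envelope is already
#' band-limited to a few hertz by the final low-pass, so plain subsampling
#' introduces no aliasing and preserves non-negativity exactly.
#'
#' @param env an `envelope_series`.
#' @param target_fs target rate in Hz; must divide `env$fs`.
#' @return an `envelope_series` at `target_fs`.
#' @export
decimate_envelope <- function(env, target_fs = 100) {
  stopifnot(inherits(env, "envelope_series"))
  k <- env$fs / target_fs
  if (abs(k - round(k)) > 1e-9)
    stop("fs (", env$fs, ") is not an integer multiple of target_fs (", target_fs, ")")
  k <- as.integer(round(k))
  idx <- seq(1, ncol(env$values), by = k)
  envelope_series(env$values[, idx, drop = FALSE], target_fs, env$muscle_names)
}

#' Detect multi-muscle EMG activation onset
#'
#' Adaptive-threshold detector on the sum of all channel envelopes. At each
#' sample n the threshold is T[n] = mu + h * sigma, where mu and sigma are
#' the mean and standard deviation of the summed envelope over the trailing
#' window that ends at sample n-1 (the current sample is excluded, so a
#' rising signal cannot inflate its own threshold). Onset is the first
#' sample whose summed envelope strictly exceeds T. One reach per trial is
#' assumed: only the first crossing is reported.
#'
#' @param env an `envelope_series` at the rate the online system uses
#'   (default 100 Hz control rate; a 1 kHz mode works the same way).
#' @param gain_h threshold gain h (> 0).
#' @param window_ms trailing window length in milliseconds.
#' @return a list of class `onset_event` with `index` (1-based sample),
#'   `time_s`, `threshold_trace` and `sum_trace`, or `NULL` when the summed
#'   envelope never exceeds the threshold.
#' @export
detect_onset <- function(env, gain_h = default_config()$onset$gain_h,
                         window_ms = default_config()$onset$window_ms) {
  stopifnot(inherits(env, "envelope_series"), gain_h > 0)
  w <- as.integer(round(window_ms / 1000 * env$fs))
  s <- colSums(env$values)
  n <- length(s)
  if (n < w + 1) stop("trial shorter than one onset window (", w, " samples)")

  cs <- cumsum(c(0, s)); cs2 <- cumsum(c(0, s^2))
  idx <- (w + 1):n
  mu <- (cs[idx] - cs[idx - w]) / w
  v <- pmax((cs2[idx] - cs2[idx - w]) / w - mu^2, 0)
  thr <- c(rep(NA_real_, w), mu + gain_h * sqrt(v))

  hit <- which(s[idx] > thr[idx])
  if (!length(hit)) return(NULL)
  i <- idx[hit[1]]
  structure(list(index = i, time_s = (i - 1) / env$fs,
                 threshold_trace = thr, sum_trace = s),
            class = "onset_event")
}
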