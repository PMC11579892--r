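#' Default ground-truth synergy matrix for synthetic sessions
#'
#' Six muscles by four synergies, unit-norm columns. The first synergy is
#' flexor-dominant (biceps brachii, anterior deltoid) and preferred toward
#' N; the second extensor-dominant (triceps brachii, posterior deltoid),
#' preferred toward S; the remaining two load the medial deltoid / trapezius
#' groups and prefer E and W, mirroring the observed tuning of flexors to
#' northward and extensors to southward targets.
#'
#' @return 6x4 non-negative matrix with unit-norm columns.
#' @export
default_w_true <- function() {
  W <- cbind(
    flex  = c(0.80, 0.05, 0.70, 0.20, 0.05, 0.25),
    ext   = c(0.05, 0.80, 0.05, 0.25, 0.70, 0.10),
    east  = c(0.10, 0.30, 0.15, 0.75, 0.35, 0.10),
    west  = c(0.30, 0.05, 0.25, 0.10, 0.10, 0.80))
  rownames(W) <- default_muscles()
  sweep(W, 2, sqrt(colSums(W^2)), "/")
}

#' Configuration for the synthetic-session generator
#'
#' Defines the study conditions emulated by the generator: direction-tuned,
#' synergy-driven envelopes with bell-shaped activation profiles peaking
#' mid-movement, additive non-negative noise, an electromechanical delay
#' between EMG and kinematic onset, and minimum-jerk reaches to eight
#' targets on a circle around home.
#'
#' @param seed session RNG seed.
#' @param n_train,n_test trials per direction for training and test.
#' @param W_true ground-truth synergy matrix (muscles x 4).
#' @param preferred_angles_deg preferred direction of each synergy.
#' @param tuning_exponent p in max(0, cos(theta - phi))^p; p = 0 removes all
#'   direction tuning (chance-floor construction), p = 1 is plain cosine
#'   tuning.
#' @param amplitude peak activation amplitude.
#' @param amplitude_cv trial-to-trial coefficient of variation of movement
#'   vigor (lognormal multiplier on all synergy amplitudes).
#' @param activation_cv within-trial coefficient of variation of each
#'   synergy's activation trace (smooth multiplicative noise), emulating
#'   neuromotor drive variability; this is the scatter the per-direction
#'   mixture models are meant to capture.
#' @param angle_jitter_deg standard deviation of the executed movement
#'   direction around the instructed target direction.
#' @param snr ratio of peak activation to noise scale.
#' @param baseline_level constant resting envelope level.
#' @param bell_peak_frac peak location as a fraction of movement duration.
#' @param bell_width_frac Gaussian bell sigma as a fraction of duration. The
#'   bell is truncated at the EMG onset, so activation switches on as a
#'   burst (a step to the bell's tail value) and then follows the bell;
#'   muscle bursts begin abruptly even when the overall profile is
#'   bell-shaped.
#' @param endpoint_sd_m standard deviation of the final hand position
#'   scatter around the target, per horizontal axis.
#' @param electromechanical_delay_s lag from EMG onset to kinematic onset.
#' @param movement_duration_s reach duration.
#' @param pre_s,post_s baseline before EMG onset and hold after the reach.
#' @param layout a [target_layout()].
#' @param control_hz,raw_hz sampling rates.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(seed = 1, n_train = 10, n_test = 20,
                             W_true = default_w_true(),
                             preferred_angles_deg = c(90, 270, 0, 180),
                             tuning_exponent = 1,
                             amplitude = 1, amplitude_cv = 0.15,
                             activation_cv = 0.2, angle_jitter_deg = 5,
                             snr = 20, baseline_level = 0.1,
                             bell_peak_frac = 0.5, bell_width_frac = 0.25,
                             endpoint_sd_m = 0.01,
                             electromechanical_delay_s = 0.1,
                             movement_duration_s = 1.2,
                             pre_s = 1.0, post_s = 0.4,
                             layout = target_layout(),
                             control_hz = 100, raw_hz = 1000) {
  stopifnot(all(W_true >= 0), snr > 0, bell_peak_frac > 0, bell_peak_frac < 1,
            tuning_exponent >= 0)
  structure(as.list(environment()), class = "generator_config")
}

#' Minimum-jerk trajectory between two points
#'
#' Position follows the fifth-order polynomial s(t) = 10 t^3 - 15 t^4 +
#' 6 t^5 of normalized time, giving zero velocity and acceleration at both
#' ends.
#'
#' @param from,to endpoint 3-vectors.
#' @param duration_s movement time.
#' @param fs sampling rate in Hz.
#' @return list with `position` ((n+1) x 3) and `velocity` ((n+1) x 3)
#'   sampled at t = 0, 1/fs, ..., duration_s.
#' @export
min_jerk <- function(from, to, duration_s, fs) {
  tt <- seq(0, duration_s, by = 1 / fs)
  tau <- tt / duration_s
  s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  sd <- (30 * tau^2 - 60 * tau^3 + 30 * tau^4) / duration_s
  d <- to - from
  list(position = outer(s, d) + matrix(from, length(tt), 3, byrow = TRUE),
       velocity = outer(sd, d),
       time_s = tt)
}

# half-rectified cosine tuning of synergy amplitudes to a movement angle
synergy_tuning <- function(direction, cfg, angle_deg = NULL) {
  th <- (angle_deg %||% direction_angle(direction)) * pi / 180
  phi <- cfg$preferred_angles_deg * pi / 180
  base <- pmax(0, cos(th - phi))
  if (cfg$tuning_exponent == 0) rep(1, length(phi)) else base^cfg$tuning_exponent
}

# nominal peak channel envelope (incl. baseline) over all directions;
# reference level at which the configured snr applies
session_peak_envelope <- function(cfg) {
  tuning <- vapply(DIRECTIONS, synergy_tuning, numeric(ncol(cfg$W_true)), cfg = cfg)
  max(cfg$W_true %*% (cfg$amplitude * tuning)) + cfg$baseline_level
}

# colored baseline noise: i.i.d. Gaussian low-pass filtered to the envelope
# bandwidth (4 Hz), rescaled to unit standard deviation
smooth_noise <- function(n_ch, n, fs) {
  lp <- signal::butter(2, 4 / (fs / 2), type = "low")
  g <- sqrt(sum(signal::filter(lp$b, lp$a, c(1, rep(0, 4 * fs)))^2))
  t(vapply(seq_len(n_ch), function(i)
    as.numeric(signal::filter(lp$b, lp$a, stats::rnorm(n))) / g, numeric(n)))
}

#' Generate one synthetic trial
#'
#' Activation of each synergy is its direction tuning times a Gaussian bell
#' peaking at `bell_peak_frac` of the movement duration after EMG onset.
#' Envelopes are W_true c(t) + baseline + truncated-Gaussian noise (clipped
#' at zero). The hand trajectory is a minimum-jerk reach from home to the
#' target that starts one electromechanical delay after EMG onset and then
#' holds at the target.
#'
#' @param direction a direction name.
#' @param cfg a `generator_config`.
#' @return list of class `synthetic_trial`: `envelope` (an
#'   `envelope_series` at the control rate), `onset_index` (true EMG onset,
#'   1-based), `trajectory` (samples x 3 in the home frame), `direction`,
#'   `time_s`.
#' @export
generate_trial <- function(direction, cfg) {
  fs <- cfg$control_hz
  n_pre <- as.integer(round(cfg$pre_s * fs))
  n_mov <- as.integer(round(cfg$movement_duration_s * fs))
  n_post <- as.integer(round(cfg$post_s * fs))
  n_del <- as.integer(round(cfg$electromechanical_delay_s * fs))
  n <- n_pre + n_del + n_mov + n_post
  tt <- (seq_len(n) - 1) / fs

  onset_idx <- n_pre + 1L
  t_on <- tt[onset_idx]
  angle <- direction_angle(direction) + stats::rnorm(1, 0, cfg$angle_jitter_deg)
  vigor <- stats::rlnorm(1, -cfg$amplitude_cv^2 / 2, cfg$amplitude_cv)
  tune <- synergy_tuning(direction, cfg, angle_deg = angle)
  t_peak <- t_on + cfg$bell_peak_frac * cfg$movement_duration_s
  sig <- cfg$bell_width_frac * cfg$movement_duration_s
  bell <- exp(-(tt - t_peak)^2 / (2 * sig^2))
  bell[tt < t_on] <- 0                          # burst onset: step to the tail value
  C <- outer(cfg$amplitude * vigor * tune, bell)  # n_syn x n
  if (cfg$activation_cv > 0)
    C <- pmax(C * (1 + cfg$activation_cv * smooth_noise(nrow(C), n, fs)), 0)
  clean <- cfg$W_true %*% C + cfg$baseline_level
  # constant-SNR noise: a smoothed, rectified signal fluctuates in
  # proportion to its level; the stated snr applies at peak activation
  peak_ref <- session_peak_envelope(cfg)
  sd_t <- (cfg$amplitude / cfg$snr) * clean / peak_ref
  E <- pmax(clean + sd_t * smooth_noise(nrow(cfg$W_true), n, fs), 0)
  rownames(E) <- rownames(cfg$W_true)

  # kinematics: still until onset + delay, min-jerk reach, hold at target
  kin_start <- onset_idx + n_del
  target <- cfg$layout$targets[direction, ]
  target[1:2] <- target[1:2] + stats::rnorm(2, 0, cfg$endpoint_sd_m)
  mj <- min_jerk(cfg$layout$home, target, cfg$movement_duration_s, fs)
  traj <- matrix(cfg$layout$home, n, 3, byrow = TRUE)
  idx <- kin_start:min(n, kin_start + nrow(mj$position) - 1L)
  traj[idx, ] <- mj$position[seq_along(idx), ]
  if (max(idx) < n) traj[(max(idx) + 1L):n, ] <- matrix(target, n - max(idx), 3, byrow = TRUE)

  structure(list(envelope = envelope_series(E, fs),
                 onset_index = onset_idx,
                 trajectory = traj, direction = direction, time_s = tt),
            class = "synthetic_trial")
}

#' Generate a pure-baseline (rest) trial
#'
#' Envelopes fluctuate around the resting level with the same constant-SNR
#' noise model as active trials but no synergy activation: the input for
#' false-positive testing of the onset detector.
#'
#' @param cfg a `generator_config`.
#' @param duration_s trial length in seconds.
#' @return an `envelope_series` at the control rate.
#' @export
generate_baseline_trial <- function(cfg, duration_s = 5) {
  fs <- cfg$control_hz
  n <- as.integer(round(duration_s * fs))
  sd_rest <- (cfg$amplitude / cfg$snr) * cfg$baseline_level / session_peak_envelope(cfg)
  E <- pmax(cfg$baseline_level + sd_rest * smooth_noise(nrow(cfg$W_true), n, fs), 0)
  rownames(E) <- rownames(cfg$W_true)
  envelope_series(E, fs)
}

#' Generate a raw-EMG-like trial at the raw sampling rate
#'
#' Amplitude-modulates band-limited Gaussian noise (a crude interference
#' surrogate for surface EMG) with the envelope profile of a synthetic
#' trial, for exercising the envelope-extraction chain. Physiological
#' detail (motor-unit structure) is not modeled.
#'
#' @inheritParams generate_trial
#' @return an `emg_trial` at `cfg$raw_hz`.
#' @export
generate_raw_trial <- function(direction, cfg) {
  st <- generate_trial(direction, cfg)
  k <- as.integer(round(cfg$raw_hz / cfg$control_hz))
  prof <- apply(st$envelope$values, 1, function(x) rep(x, each = k))  # time x ch
  n <- nrow(prof)
  carrier <- matrix(stats::rnorm(n * ncol(prof)), n, ncol(prof))
  # scale so the rectified mean matches the envelope profile
  raw <- t(carrier * prof) * sqrt(pi / 2)
  emg_trial(raw, fs_raw = cfg$raw_hz, muscle_names = rownames(st$envelope$values),
            direction = direction)
}

#' Generate a full seeded synthetic session
#'
#' Produces `n_train` training and `n_test` test trials per direction, each
#' set in an independently randomized direction order, plus per-muscle MVC
#' surrogates (120 percent of the maximum attainable noise-free envelope).
#' Fully reproducible from `cfg$seed`.
#'
#' @param cfg a `generator_config`.
#' @return list of class `synthetic_session` with `train` and `test` (lists
#'   of `synthetic_trial`), `mvc`, `cfg`.
#' @export
generate_session <- function(cfg) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(cfg$seed)
  make_set <- function(n_per) {
    dirs <- sample(rep(DIRECTIONS, n_per))
    lapply(dirs, generate_trial, cfg = cfg)
  }
  train <- make_set(cfg$n_train)
  test <- make_set(cfg$n_test)
  tuning <- vapply(DIRECTIONS, synergy_tuning, numeric(ncol(cfg$W_true)), cfg = cfg)
  mvc <- stats::setNames(
    1.2 * (apply(cfg$W_true %*% (cfg$amplitude * tuning), 1, max) + cfg$baseline_level),
    rownames(cfg$W_true))
  structure(list(train = train, test = test, mvc = mvc, cfg = cfg),
            class = "synthetic_session")
}

#' Train a decoder on a synthetic session's training set
#'
#' Runs onset detection on every training trial and fits the full decoder
#' (NMF synergies + per-direction GMMs) on the detected segments.
#'
#' @param session a `synthetic_session`.
#' @param gain_h onset-detector gain.
#' @param ... passed to [train_decoder()].
#' @return a `decoder_model`.
#' @export
train_on_session <- function(session, gain_h = default_config()$onset$gain_h, ...) {
  envs <- lapply(session$train, `[[`, "envelope")
  dirs <- vapply(session$train, `[[`, character(1), "direction")
  onsets <- lapply(envs, detect_onset, gain_h = gain_h)
  train_decoder(envs, dirs, onsets, seed = session$cfg$seed, ...)
}

#' Decode a synthetic session's test set
#'
#' @param session a `synthetic_session`.
#' @param model a `decoder_model`.
#' @param gain_h onset-detector gain.
#' @return list with `traces` (posterior traces, NULL for excluded trials),
#'   `true_dirs`, `est_dirs` (NA for excluded), `excluded` flags,
#'   `onsets` (detected onset indices, NA when missing).
#' @export
decode_session <- function(session, model, gain_h = default_config()$onset$gain_h) {
  n <- length(session$test)
  traces <- vector("list", n)
  true_dirs <- vapply(session$test, `[[`, character(1), "direction")
  est_dirs <- rep(NA_character_, n)
  onsets <- rep(NA_integer_, n)
  excluded <- rep(FALSE, n)
  for (i in seq_len(n)) {
    tr <- session$test[[i]]
    on_i <- detect_onset(tr$envelope, gain_h = gain_h)
    if (is.null(on_i) ||
        on_i$index + round(model$t_acc_s * model$control_fs) > ncol(tr$envelope$values)) {
      excluded[i] <- TRUE
      next
    }
    onsets[i] <- on_i$index
    traces[[i]] <- decode_trial(tr$envelope, on_i, model)
    est_dirs[i] <- traces[[i]]$final_estimate
  }
  list(traces = traces, true_dirs = true_dirs, est_dirs = est_dirs,
       excluded = excluded, onsets = onsets)
}
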