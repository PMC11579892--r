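#' Classify a direction estimate error by circular distance
#'
#' The error taxonomy follows the target geometry: distance 1 (45 deg,
#' adjacent) is a type-1 error, 2 (perpendicular) type 2, 3 (near-opposite)
#' type 3 and 4 (opposite) type 4; distance 0 is correct.
#'
#' @param true_d,est_d direction names or 0-based indices.
#' @return one of "correct", "type1".."type4".
#' @export
classify_error <- function(true_d, est_d) {
  d <- direction_distance(true_d, est_d)
  c("correct", "type1", "type2", "type3", "type4")[d + 1L]
}

#' Target layout for the center-out task
#'
#' Eight targets equally spaced on a circle of radius `radius_m` around the
#' home position, in the horizontal plane through home, at the direction
#' angles (adjacent spacing 45 deg).
#'
#' @param home home position 3-vector.
#' @param radius_m circle radius in meters (default 0.25).
#' @return object of class `target_layout` with a `targets` 8x3 matrix in
#'   [DIRECTIONS] order.
#' @export
target_layout <- function(home = c(0, 0, 0), radius_m = 0.25) {
  ang <- DIRECTION_ANGLES_DEG * pi / 180
  targets <- cbind(home[1] + radius_m * cos(ang),
                   home[2] + radius_m * sin(ang),
                   home[3])
  rownames(targets) <- DIRECTIONS
  structure(list(home = home, radius_m = radius_m, targets = targets),
            class = "target_layout")
}

#' Cartesian-to-polar transform in the home frame
#'
#' @param p 2-vector (x, y) relative to home.
#' @return list with `rho` (meters) and `theta_deg` (counter-clockwise from
#'   +x, in [0, 360); NA and `theta_undefined = TRUE` when rho = 0).
#' @export
to_polar <- function(p) {
  stopifnot(all(is.finite(p)))
  rho <- sqrt(sum(p[1:2]^2))
  if (rho == 0)
    return(list(rho = 0, theta_deg = NA_real_, theta_undefined = TRUE))
  th <- atan2(p[2], p[1]) * 180 / pi
  list(rho = rho, theta_deg = th %% 360, theta_undefined = FALSE)
}

# smallest absolute angular difference, result in [0, 180]
wrap_angle_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Repeatability errors between assisted end point and transparent centroid
#'
#' Expresses the discrepancy between an assisted movement's final hand
#' position and the centroid of the transparent movements toward the same
#' target as an absolute radial difference (hand advancement) and an
#' absolute wrapped angular difference.
#'
#' @param final_assist 2-vector, final assisted hand position in home frame.
#' @param centroid_transparent 2-vector, mean transparent final position.
#' @return list with `delta_rho_m` and `delta_theta_deg` (<= 180), or an
#'   `excluded` flag with a reason when an angle is undefined.
#' @export
repeatability_errors <- function(final_assist, centroid_transparent) {
  pa <- to_polar(final_assist)
  pc <- to_polar(centroid_transparent)
  if (isTRUE(pa$theta_undefined) || isTRUE(pc$theta_undefined))
    return(list(delta_rho_m = NA_real_, delta_theta_deg = NA_real_,
                excluded = TRUE, reason = "undefined angle at zero radius"))
  list(delta_rho_m = abs(pa$rho - pc$rho),
       delta_theta_deg = wrap_angle_diff(pa$theta_deg, pc$theta_deg),
       excluded = FALSE)
}

#' Integrated EMG of a movement segment
#'
#' Normalizes each channel by its MVC (as a percentage) and time between 0
#' and 1, then integrates with the trapezoidal rule: a constant envelope at
#' MVC level integrates to 100.
#'
#' @param env an `envelope_series` spanning onset to movement end.
#' @param mvc named per-muscle MVC amplitudes.
#' @return named per-muscle iEMG values.
#' @export
iemg <- function(env, mvc) {
  stopifnot(inherits(env, "envelope_series"))
  if (is.null(mvc)) stop("MVC values are required to normalize iEMG")
  mvc <- mvc[env$muscle_names]
  if (anyNA(mvc) || any(mvc <= 0)) stop("missing or non-positive MVC for some muscle")
  n <- ncol(env$values)
  if (n < 2) stop("segment too short to integrate")
  tt <- seq(0, 1, length.out = n)
  vapply(seq_len(nrow(env$values)), function(i)
    pracma::trapz(tt, env$values[i, ] / mvc[i] * 100), numeric(1)) |>
    stats::setNames(env$muscle_names)
}

#' Movement end by the 20 percent-of-peak rule
#'
#' Non-causal segmentation used offline: the end of the movement is the
#' first sample after the global displacement peak where the series drops
#' to at most 20 percent of that peak. If it never drops that far the last
#' sample is returned with `reached_threshold = FALSE`.
#'
#' @param displacement non-negative scalar time series with a positive peak.
#' @param frac threshold fraction of the peak (default 0.2).
#' @return list with `index` (1-based) and `reached_threshold`.
#' @export
movement_end <- function(displacement, frac = 0.2) {
  pk <- which.max(displacement)
  peak <- displacement[pk]
  if (!is.finite(peak) || peak <= 0) stop("series has no positive peak")
  after <- which(displacement[(pk + 1):length(displacement)] <= frac * peak)
  if (pk == length(displacement) || !length(after))
    return(list(index = length(displacement), reached_threshold = FALSE))
  list(index = pk + after[1], reached_threshold = TRUE)
}

#' Kinematics-based direction classifier (offline benchmark)
#'
#' At each sample the hand's polar angle in the home frame is assigned to
#' the direction whose target angle minimizes the wrapped absolute
#' difference (45-degree bins; exact bin-edge ties go to the
#' lower-index direction). Samples with displacement below `min_disp`
#' inherit the previous estimate, starting from "E" (the uniform-start
#' rule), so angle noise at the home position does not produce estimates.
#'
#' @param trajectory matrix of hand positions in the home frame, samples x
#'   2 (or x 3; only x and y are used).
#' @param min_disp minimum displacement in meters before the angle is
#'   trusted (default 0.01).
#' @return character vector of per-sample direction estimates.
#' @export
kinematic_benchmark <- function(trajectory, min_disp = 0.01) {
  trajectory <- as.matrix(trajectory)
  n <- nrow(trajectory)
  out <- character(n)
  prev <- "E"
  for (k in seq_len(n)) {
    p <- to_polar(trajectory[k, 1:2])
    if (isTRUE(p$theta_undefined) || p$rho < min_disp) {
      out[k] <- prev
    } else {
      d <- wrap_angle_diff(p$theta_deg, DIRECTION_ANGLES_DEG)
      out[k] <- DIRECTIONS[which.min(d)]  # which.min: first = lowest index
      prev <- out[k]
    }
  }
  out
}

#' Chance level adjusted for the number of trials
#'
#' The accuracy that a random classifier would not exceed with the stated
#' confidence: the smallest count k whose Binomial(n_trials, 1/n_classes)
#' CDF reaches the upper tail bound of the two-sided interval
#' (1 - (1-confidence)/2), reported as a percentage 100 k / n_trials. For
#' 160 trials over 8 classes at 95 percent confidence this gives 18.125.
#'
#' @param n_trials number of scored trials.
#' @param n_classes number of equiprobable classes.
#' @param confidence two-sided confidence level (default 0.95).
#' @return percentage.
#' @export
adjusted_chance_level <- function(n_trials, n_classes, confidence = 0.95) {
  stopifnot(n_trials >= 1, n_classes >= 2)
  upper <- 1 - (1 - confidence) / 2
  k <- min(which(stats::pbinom(0:n_trials, n_trials, 1 / n_classes) >= upper)) - 1L
  100 * k / n_trials
}

#' Session-level performance metrics
#'
#' Aggregates per-trial decoding results into the confusion matrix,
#' accuracy and error-type percentages (over non-excluded trials; they sum
#' to 100), modified accuracy (correct + type 1), the adjusted chance level
#' for the scored trial count, and optional repeatability / manipulability /
#' iEMG summaries.
#'
#' @param true_dirs,est_dirs per-trial true and estimated direction names.
#' @param excluded logical per-trial exclusion flags (default none).
#' @param delta_rho_m,delta_theta_deg,manipulability optional per-trial values.
#' @param confidence confidence for the adjusted chance level.
#' @return object of class `session_metrics`.
#' @export
session_metrics <- function(true_dirs, est_dirs, excluded = rep(FALSE, length(true_dirs)),
                            delta_rho_m = NULL, delta_theta_deg = NULL,
                            manipulability = NULL, confidence = 0.95) {
  stopifnot(length(true_dirs) == length(est_dirs))
  keep <- !excluded
  if (!any(keep)) stop("no non-excluded trials")
  td <- factor(true_dirs[keep], levels = DIRECTIONS)
  ed <- factor(est_dirs[keep], levels = DIRECTIONS)
  confusion <- table(true = td, estimated = ed)
  n <- sum(keep)
  types <- vapply(which(keep), function(i) classify_error(true_dirs[i], est_dirs[i]), character(1))
  counts <- table(factor(types, levels = c("correct", "type1", "type2", "type3", "type4")))
  pct <- 100 * as.numeric(counts) / n
  names(pct) <- names(counts)
  structure(list(
    confusion = confusion,
    n_trials = n, n_excluded = sum(excluded),
    accuracy_pct = pct[["correct"]],
    type1_pct = pct[["type1"]], type2_pct = pct[["type2"]],
    type3_pct = pct[["type3"]], type4_pct = pct[["type4"]],
    modified_accuracy_pct = pct[["correct"]] + pct[["type1"]],
    chance_level_pct = adjusted_chance_level(n, 8, confidence),
    delta_rho_m = delta_rho_m, delta_theta_deg = delta_theta_deg,
    manipulability = manipulability),
    class = "session_metrics")
}

#' @export
print.session_metrics <- function(x, ...) {
  cat(sprintf("<session_metrics> %d trials (%d excluded)\n", x$n_trials, x$n_excluded))
  cat(sprintf("  accuracy %.1f%% | modified %.1f%% | type1 %.1f%% type2 %.1f%% type3 %.1f%% type4 %.1f%%\n",
              x$accuracy_pct, x$modified_accuracy_pct, x$type1_pct, x$type2_pct,
              x$type3_pct, x$type4_pct))
  cat(sprintf("  adjusted chance level %.1f%%\n", x$chance_level_pct))
  invisible(x)
}

#' Modified accuracy as a function of time since onset
#'
#' For every control step from `from_s` to the accumulation time, the
#' fraction of trials whose running estimate at that step is correct or a
#' type-1 (adjacent) error.
#'
#' @param traces list of `posterior_trace` objects (or character matrices /
#'   vectors of running estimates).
#' @param true_dirs per-trial true directions.
#' @param from_s first time to report, seconds after onset (default 0.05).
#' @return data.frame with `time_s` and `modified_accuracy_pct`.
#' @export
accuracy_vs_time <- function(traces, true_dirs, from_s = 0.05) {
  est <- lapply(traces, function(tr) if (inherits(tr, "posterior_trace")) tr$estimates else tr)
  n_it <- unique(vapply(est, length, integer(1)))
  if (length(n_it) != 1) stop("traces have differing lengths")
  fs <- if (inherits(traces[[1]], "posterior_trace")) traces[[1]]$control_fs else 100
  k0 <- max(1L, as.integer(round(from_s * fs)))
  ks <- k0:n_it
  mod <- vapply(ks, function(k) {
    ok <- mapply(function(e, t) direction_distance(t, e[k]) <= 1, est, true_dirs)
    100 * mean(ok)
  }, numeric(1))
  data.frame(time_s = ks / fs, modified_accuracy_pct = mod)
}

#' Tidy per-trial results table
#'
#' @param true_dirs,est_dirs per-trial directions.
#' @param excluded logical flags.
#' @param delta_rho_m,delta_theta_deg,manipulability optional per-trial values.
#' @return data.frame, one row per trial, ready for any stats tool.
#' @export
trial_table <- function(true_dirs, est_dirs, excluded = rep(FALSE, length(true_dirs)),
                        delta_rho_m = NA_real_, delta_theta_deg = NA_real_,
                        manipulability = NA_real_) {
  data.frame(
    trial = seq_along(true_dirs),
    true_dir = true_dirs, est_dir = est_dirs,
    error_type = mapply(classify_error, true_dirs, est_dirs),
    delta_rho_m = delta_rho_m, delta_theta_deg = delta_theta_deg,
    manipulability = manipulability, excluded = excluded,
    row.names = NULL)
}
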