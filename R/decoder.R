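#' Assemble a trained direction decoder
#'
#' @param synergy a `synergy_model`.
#' @param gmms named list of eight `direction_gmm` objects in [DIRECTIONS] order.
#' @param t_acc_s accumulation time in seconds: the window after EMG onset
#'   during which the estimate may change; frozen thereafter (default 0.6).
#' @param control_fs control-loop rate in Hz (default 100).
#' @return an object of class `decoder_model`.
#' @export
decoder_model <- function(synergy, gmms, t_acc_s = 0.6, control_fs = 100) {
  stopifnot(inherits(synergy, "synergy_model"), t_acc_s > 0)
  if (length(gmms) != 8 || !identical(names(gmms), DIRECTIONS))
    stop("gmms must be a named list of 8 mixtures in DIRECTIONS order")
  structure(list(synergy = synergy, gmms = gmms,
                 t_acc_s = t_acc_s, control_fs = control_fs),
            class = "decoder_model")
}

#' @export
print.decoder_model <- function(x, ...) {
  cat(sprintf("<decoder_model> %d synergies, 8 direction GMMs, t_acc = %g s @ %g Hz\n",
              x$synergy$n_syn, x$t_acc_s, x$control_fs))
  invisible(x)
}

#' Per-direction conditional probabilities of one activation sample
#'
#' Evaluates each direction's mixture density at the activation vector and
#' normalizes the eight values to sum to one (uniform prior over directions;
#' targets are presented in randomized order). Densities are evaluated in
#' the log domain; if all eight underflow to zero the uniform vector is
#' returned with a warning (degenerate-evidence rule).
#'
#' @param c_k non-negative activation vector (length n_syn).
#' @param model a `decoder_model` (or bare list of 8 `direction_gmm`s).
#' @return normalized probability 8-vector named by direction.
#' @export
direction_likelihoods <- function(c_k, model) {
  gmms <- if (inherits(model, "decoder_model")) model$gmms else model
  logd <- vapply(gmms, function(g) dgmm(c_k, g, log = TRUE), numeric(1))
  if (all(!is.finite(logd))) {
    warning("all direction densities underflowed; returning uniform evidence")
    return(stats::setNames(rep(1 / 8, 8), DIRECTIONS))
  }
  p <- exp(logd - max(logd, na.rm = TRUE))
  p[!is.finite(p)] <- 0
  stats::setNames(p / sum(p), DIRECTIONS)
}

#' Recursive Bayesian evidence accumulation
#'
#' Multiplies the previous cumulative probability vector element-wise with
#' the new per-sample likelihood vector and renormalizes: the recursive form
#' of accumulating conditional evidence under per-sample independence. The
#' first iteration starts from a uniform prior. If the product underflows to
#' all zeros the previous vector is kept with a warning.
#'
#' @param prev previous cumulative probability 8-vector (normalized).
#' @param likelihoods per-sample probability 8-vector (normalized).
#' @return normalized cumulative probability 8-vector.
#' @export
accumulate_evidence <- function(prev, likelihoods) {
  p <- prev * likelihoods
  s <- sum(p)
  if (s == 0 || !is.finite(s)) {
    warning("evidence product underflowed; keeping previous cumulative vector")
    return(prev)
  }
  p / s
}

#' Direction estimate from cumulative probabilities
#'
#' Argmax with a deterministic tie-break: on exact ties the direction with
#' the lowest index in [DIRECTIONS] order wins.
#'
#' @param p_cum normalized probability 8-vector.
#' @return direction name.
#' @export
estimate_direction <- function(p_cum) {
  DIRECTIONS[which.max(p_cum)]
}

#' Decode one trial online
#'
#' Runs the online loop from the detected EMG onset for `t_acc_s` seconds:
#' at each control iteration the activation coefficients are estimated by
#' non-negative least squares, converted to per-direction probabilities and
#' accumulated; the running estimate is the argmax of the cumulative vector.
#' After the accumulation time the estimate is frozen.
#'
#' @param env an `envelope_series` at the decoder's control rate.
#' @param onset an `onset_event` (or 1-based onset sample index).
#' @param model a `decoder_model`.
#' @return a `posterior_trace`: matrices `likelihoods` and `p_cum`
#'   (iterations x 8), character vector `estimates`, `final_estimate`,
#'   `n_iterations`, `onset_index`.
#' @export
decode_trial <- function(env, onset, model) {
  stopifnot(inherits(env, "envelope_series"), inherits(model, "decoder_model"))
  if (abs(env$fs - model$control_fs) > 1e-9)
    stop("envelope rate ", env$fs, " Hz does not match control rate ",
         model$control_fs, " Hz")
  if (is.null(onset)) stop("trial excluded: no onset detected")
  i0 <- if (inherits(onset, "onset_event")) onset$index else as.integer(onset)
  n_it <- as.integer(round(model$t_acc_s * model$control_fs))
  if (i0 + n_it > ncol(env$values))
    stop("trial excluded: envelope ends ", i0 + n_it - ncol(env$values),
         " samples before the accumulation window completes")

  lik <- pc <- matrix(NA_real_, n_it, 8, dimnames = list(NULL, DIRECTIONS))
  est <- character(n_it)
  p_cum <- rep(1 / 8, 8)
  for (k in seq_len(n_it)) {
    c_k <- estimate_activations(env$values[, i0 + k], model$synergy)
    l_k <- direction_likelihoods(c_k, model)
    p_cum <- accumulate_evidence(p_cum, l_k)
    lik[k, ] <- l_k; pc[k, ] <- p_cum
    est[k] <- estimate_direction(p_cum)
  }
  structure(list(likelihoods = lik, p_cum = pc, estimates = est,
                 final_estimate = est[n_it], n_iterations = n_it,
                 onset_index = i0, control_fs = model$control_fs),
            class = "posterior_trace")
}

#' @export
print.posterior_trace <- function(x, ...) {
  cat(sprintf("<posterior_trace> %d iterations @ %g Hz, final estimate %s (P = %.3f)\n",
              x$n_iterations, x$control_fs, x$final_estimate,
              max(x$p_cum[x$n_iterations, ])))
  invisible(x)
}

#' Train a full decoder from labeled training envelopes
#'
#' Convenience wrapper over the offline procedure: per-trial envelope
#' segments from onset to onset + t_acc are concatenated along time, muscle
#' synergies are extracted by NMF, the resulting activation coefficients are
#' labeled with each trial's direction, and one Gaussian mixture per
#' direction is fitted.
#'
#' @param envs list of `envelope_series` at the control rate (one per trial).
#' @param directions per-trial direction labels.
#' @param onsets per-trial onset events or indices (NULL entries are skipped).
#' @param n_syn number of synergies.
#' @param t_acc_s,control_fs accumulation time and control rate.
#' @param seed seed for NMF restarts and GMM initialization.
#' @param ... passed to [extract_synergies()].
#' @return a `decoder_model`.
#' @export
train_decoder <- function(envs, directions, onsets, n_syn = 4,
                          t_acc_s = 0.6, control_fs = 100, seed = 1, ...) {
  n_it <- as.integer(round(t_acc_s * control_fs))
  segs <- list(); labs <- character(0)
  for (i in seq_along(envs)) {
    on_i <- onsets[[i]]
    if (is.null(on_i)) next
    i0 <- if (inherits(on_i, "onset_event")) on_i$index else as.integer(on_i)
    if (i0 + n_it > ncol(envs[[i]]$values)) next
    segs[[length(segs) + 1]] <- envs[[i]]$values[, (i0 + 1):(i0 + n_it), drop = FALSE]
    labs <- c(labs, rep(directions[i], n_it))
  }
  if (!length(segs)) stop("no usable training trials (onsets missing or too late)")
  E <- do.call(cbind, segs)
  fit <- extract_synergies(E, n_syn = n_syn, seed = seed, ...)
  H <- activation_series(fit$H$H, fs = control_fs, labels = labs)
  gmms <- train_gmms(H, seed = seed)
  decoder_model(fit$model, gmms, t_acc_s = t_acc_s, control_fs = control_fs)
}
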