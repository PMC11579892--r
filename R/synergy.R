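#' Extract muscle synergies by non-negative matrix factorization
#'
#' Factorizes the non-negative envelope matrix E (muscles x time) as
#' E ~ W H with W (muscles x n_syn) the synergy weights and H
#' (n_syn x time) the activation coefficients, minimizing the
#' root-mean-squared residual by multiplicative updates. Each update is
#' guaranteed not to increase the residual, so the objective is monotone
#' non-increasing across iterations. The factorization is a local search:
#' `restarts` random initializations are run and the lowest-RMSE solution
#' kept. After extraction every column of W is scaled to unit Euclidean
#' norm with the inverse scale folded into H, removing the scale
#' indeterminacy so activation features are comparable between offline
#' training and online estimation.
#'
#' @param training_env an `envelope_series` (or a plain non-negative matrix,
#'   muscles x time) of concatenated training envelopes.
#' @param n_syn number of synergies (default 4).
#' @param max_iter maximum multiplicative-update iterations per restart.
#' @param tol stop when the relative RMSE change drops below this.
#' @param restarts number of seeded random initializations.
#' @param seed RNG seed for the initializations.
#' @return a list with `model` (a `synergy_model`: `W`, `n_syn`,
#'   `muscle_names`, `extraction_meta`) and `H` (an `activation_series`).
#' @export
extract_synergies <- function(training_env, n_syn = 4, max_iter = 1000,
                              tol = 1e-6, restarts = 10, seed = 1) {
  E <- if (inherits(training_env, "envelope_series")) training_env$values else as.matrix(training_env)
  fs <- if (inherits(training_env, "envelope_series")) training_env$fs else NA_real_
  if (any(E < 0)) stop("training envelopes must be non-negative")
  if (all(E == 0)) stop("degenerate input: training matrix is all zero")
  if (n_syn > nrow(E)) stop("n_syn (", n_syn, ") exceeds number of muscles (", nrow(E), ")")
  if (ncol(E) < n_syn) stop("need at least n_syn time samples")

  best <- NULL
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  for (r in seq_len(restarts)) {
    set.seed(seed + r - 1L)
    fit <- nmf_lee_seung(E, n_syn, max_iter, tol)
    if (is.null(best) || fit$rmse < best$rmse) { best <- fit; best$restart <- r }
  }

  scale <- sqrt(colSums(best$W^2))
  scale[scale == 0] <- 1
  W <- sweep(best$W, 2, scale, "/")
  H <- sweep(best$H, 1, scale, "*")
  muscles <- rownames(E) %||% paste0("m", seq_len(nrow(E)))
  rownames(W) <- muscles

  model <- structure(list(
    W = W, n_syn = n_syn, muscle_names = muscles,
    extraction_meta = list(iterations = best$iterations, final_rmse = best$rmse,
                           restarts = restarts, seed = seed,
                           rmse_trace = best$rmse_trace)),
    class = "synergy_model")
  list(model = model,
       H = activation_series(H, fs = fs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Multiplicative updates for the Frobenius objective; eps guards division.
nmf_lee_seung <- function(E, k, max_iter, tol) {
  m <- nrow(E); n <- ncol(E)
  sc <- sqrt(mean(E) / k)
  W <- matrix(stats::runif(m * k), m, k) * sc
  H <- matrix(stats::runif(k * n), k, n) * sc
  eps <- .Machine$double.eps
  rmse <- sqrt(mean((E - W %*% H)^2))
  trace <- rmse
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    H <- H * (crossprod(W, E)) / (crossprod(W, W %*% H) + eps)
    W <- W * (E %*% t(H)) / (W %*% tcrossprod(H) + eps)
    new_rmse <- sqrt(mean((E - W %*% H)^2))
    trace <- c(trace, new_rmse)
    if (rmse - new_rmse < tol * rmse) { rmse <- new_rmse; break }
    rmse <- new_rmse
  }
  list(W = W, H = H, rmse = rmse, iterations = it, rmse_trace = trace)
}

#' Construct an activation-coefficient series
#'
#' @param H non-negative matrix, n_syn x time.
#' @param fs sampling rate in Hz (NA when samples are pooled across trials).
#' @param labels optional per-sample direction labels.
#' @return an object of class `activation_series`.
#' @export
activation_series <- function(H, fs = NA_real_, labels = NULL) {
  H <- as.matrix(H)
  if (any(H < 0)) stop("activation coefficients must be non-negative")
  if (!is.null(labels) && length(labels) != ncol(H))
    stop("labels length must equal the number of samples")
  structure(list(H = H, fs = fs, labels = labels), class = "activation_series")
}

#' @export
print.synergy_model <- function(x, ...) {
  cat(sprintf("<synergy_model> %d muscles x %d synergies (final RMSE %.4g)\n",
              nrow(x$W), x$n_syn, x$extraction_meta$final_rmse))
  invisible(x)
}

#' Estimate activation coefficients by non-negative least squares
#'
#' Solves min ||e - W c||_2 subject to c >= 0 for a single envelope sample
#' using the Lawson-Hanson active-set algorithm: exact and deterministic.
#'
#' @param e_k non-negative envelope vector (length = number of muscles).
#' @param model a `synergy_model`.
#' @return non-negative coefficient vector of length `n_syn`.
#' @export
estimate_activations <- function(e_k, model) {
  stopifnot(inherits(model, "synergy_model"))
  if (length(e_k) != nrow(model$W))
    stop("envelope vector has length ", length(e_k), " but model has ",
         nrow(model$W), " muscles")
  if (!all(is.finite(e_k))) stop("non-finite envelope values")
  as.numeric(pracma::lsqnonneg(model$W, as.numeric(e_k))$x)
}
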