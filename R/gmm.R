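#' Fit per-direction Gaussian mixture models on activation coefficients
#'
#' For each of the eight movement directions, the labeled activation
#' coefficient vectors are modeled as a weighted sum of `n_components`
#' Gaussian densities. Component means are initialized by a seeded k-means
#' run (k = n_components) and all parameters are then refined by
#' expectation-maximization with full covariances; the log-likelihood is
#' non-decreasing across EM iterations. Each M-step adds
#' `reg` x (mean data variance) to the covariance diagonals, because
#' activation features produced by non-negative least squares can contain
#' exact zeros that would otherwise make covariances singular.
#'
#' @param H_labeled an `activation_series` with per-sample direction labels.
#' @param n_components Gaussians per mixture (default 3).
#' @param seed RNG seed for k-means initialization.
#' @param reg relative diagonal regularization.
#' @param max_iter,tol EM stopping rule (relative log-likelihood change).
#' @return a named list of eight `direction_gmm` objects in [DIRECTIONS] order.
#' @export
train_gmms <- function(H_labeled, n_components = 3, seed = 1,
                       reg = 1e-6, max_iter = 200, tol = 1e-8) {
  stopifnot(inherits(H_labeled, "activation_series"))
  if (is.null(H_labeled$labels)) stop("activation series has no direction labels")
  d <- nrow(H_labeled$H)
  out <- vector("list", 8L); names(out) <- DIRECTIONS
  for (dir in DIRECTIONS) {
    X <- t(H_labeled$H[, H_labeled$labels == dir, drop = FALSE])
    if (nrow(X) < n_components * d)
      stop("direction ", dir, " has only ", nrow(X), " labeled samples; need >= ",
           n_components * d)
    out[[dir]] <- fit_gmm(X, n_components, seed = seed, reg = reg,
                          max_iter = max_iter, tol = tol)
  }
  out
}

#' Fit a single Gaussian mixture by k-means-initialized EM
#'
#' @param X data matrix, samples x dims.
#' @inheritParams train_gmms
#' @return a `direction_gmm`: `weights`, `means` (list of vectors),
#'   `covariances` (list of matrices), `loglik`, `loglik_trace`.
#' @export
fit_gmm <- function(X, n_components = 3, seed = 1, reg = 1e-6,
                    max_iter = 200, tol = 1e-8) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  ridge <- reg * mean(apply(X, 2, stats::var))
  if (!is.finite(ridge) || ridge <= 0) ridge <- reg

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  km <- suppressWarnings(stats::kmeans(X, centers = n_components, nstart = 5,
                                       iter.max = 50))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  means <- lapply(seq_len(n_components), function(j) km$centers[j, ])
  weights <- as.numeric(table(factor(km$cluster, levels = seq_len(n_components)))) / n
  weights <- pmax(weights, 1e-6); weights <- weights / sum(weights)
  covs <- lapply(seq_len(n_components), function(j) {
    Xi <- X[km$cluster == j, , drop = FALSE]
    S <- if (nrow(Xi) > d) stats::cov(Xi) else stats::cov(X)
    S + diag(ridge, d)
  })

  ll_old <- -Inf; trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    # E-step in log domain
    logd <- vapply(seq_len(n_components), function(j)
      log(weights[j]) + dmvnorm_log(X, means[[j]], covs[[j]]), numeric(n))
    mx <- apply(logd, 1, max)
    lse <- mx + log(rowSums(exp(logd - mx)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    resp <- exp(logd - lse)
    # M-step
    nk <- colSums(resp)
    weights <- nk / n
    for (j in seq_len(n_components)) {
      mu <- colSums(resp[, j] * X) / nk[j]
      Xc <- sweep(X, 2, mu)
      S <- crossprod(Xc * sqrt(resp[, j])) / nk[j] + diag(ridge, d)
      means[[j]] <- mu; covs[[j]] <- (S + t(S)) / 2
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll_old)) break
    ll_old <- ll
  }
  structure(list(weights = weights, means = means, covariances = covs,
                 loglik = trace[length(trace)], loglik_trace = trace),
            class = "direction_gmm")
}

# Row-wise multivariate normal log density via Cholesky.
dmvnorm_log <- function(X, mu, Sigma) {
  d <- length(mu)
  R <- chol(Sigma)
  Z <- forwardsolve(t(R), t(sweep(X, 2, mu)))
  -0.5 * colSums(Z^2) - sum(log(diag(R))) - 0.5 * d * log(2 * pi)
}

#' Evaluate a Gaussian mixture density
#'
#' @param x a vector (one point) or matrix (samples x dims).
#' @param gmm a `direction_gmm`.
#' @param log return the log density?
#' @return density value(s).
#' @export
dgmm <- function(x, gmm, log = FALSE) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  logd <- vapply(seq_along(gmm$weights), function(j)
    log(gmm$weights[j]) + dmvnorm_log(X, gmm$means[[j]], gmm$covariances[[j]]),
    numeric(nrow(X)))
  if (!is.matrix(logd)) logd <- matrix(logd, nrow = 1)
  mx <- apply(logd, 1, max)
  out <- mx + log(rowSums(exp(logd - mx)))
  if (log) out else exp(out)
}
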