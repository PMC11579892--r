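# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# brute-force adaptive-threshold onset scan: literal loop over samples
oracle_onset_scan <- function(s, h, w) {
  for (n in (w + 1):length(s)) {
    win <- s[(n - w):(n - 1)]
    thr <- mean(win) + h * stats::sd(win) * sqrt((w - 1) / w)  # population sd
    if (s[n] > thr) return(n)
  }
  NULL
}

# exhaustive-support non-negative least squares: try all 2^k sign supports,
# solve the restricted least squares, keep the feasible minimum
oracle_nnls <- function(A, b) {
  k <- ncol(A)
  best <- rep(0, k); best_r <- sum(b^2)
  for (m in 0:(2^k - 1)) {
    S <- which(bitwAnd(m, 2^(0:(k - 1))) > 0)
    x <- rep(0, k)
    if (length(S)) {
      xs <- tryCatch(qr.solve(A[, S, drop = FALSE], b), error = function(e) NULL)
      if (is.null(xs) || any(xs < 0)) next
      x[S] <- xs
    }
    r <- sum((b - A %*% x)^2)
    if (r < best_r - 1e-12) { best <- x; best_r <- r }
  }
  best
}

# greedy column matching by absolute cosine similarity
matched_cosines <- function(W_est, W_true) {
  cm <- abs(crossprod(W_est, W_true)) /
    outer(sqrt(colSums(W_est^2)), sqrt(colSums(W_true^2)))
  used <- integer(0); out <- numeric(0)
  for (i in order(-apply(cm, 1, max))) {
    j <- which.max(replace(cm[i, ], used, -1))
    used <- c(used, j); out <- c(out, cm[i, j])
  }
  out
}

# second, independently coded forward kinematics via homogeneous transforms
oracle_fk_homogeneous <- function(q, l1, l2) {
  Rx <- function(t) rbind(c(1, 0, 0, 0), c(0, cos(t), -sin(t), 0),
                          c(0, sin(t), cos(t), 0), c(0, 0, 0, 1))
  Ry <- function(t) rbind(c(cos(t), 0, sin(t), 0), c(0, 1, 0, 0),
                          c(-sin(t), 0, cos(t), 0), c(0, 0, 0, 1))
  Rz <- function(t) rbind(c(cos(t), -sin(t), 0, 0), c(sin(t), cos(t), 0, 0),
                          c(0, 0, 1, 0), c(0, 0, 0, 1))
  Tz <- function(d) { M <- diag(4); M[3, 4] <- d; M }
  M <- Rx(q[1]) %*% Ry(-q[2]) %*% Rz(q[3]) %*% Tz(-l1) %*% Ry(-q[4]) %*% Tz(-l2)
  M[1:3, 4]
}

# quick small session for pipeline tests
small_generator_config <- function(seed = 1, ...) {
  generator_config(seed = seed, n_train = 4, n_test = 4, ...)
}
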