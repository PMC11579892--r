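test_that("error taxonomy follows circular target distance", {
  expect_equal(classify_error("N", "NW"), "type1")
  expect_equal(classify_error("N", "W"), "type2")
  expect_equal(classify_error("N", "SW"), "type3")
  expect_equal(classify_error("N", "S"), "type4")
  expect_equal(classify_error("N", "N"), "correct")
  # exhaustive: symmetric and consistent with the index distance
  for (a in DIRECTIONS) for (b in DIRECTIONS) {
    expect_equal(classify_error(a, b), classify_error(b, a))
    d <- direction_distance(a, b)
    expect_equal(classify_error(a, b),
                 c("correct", "type1", "type2", "type3", "type4")[d + 1])
  }
})

test_that("session percentages sum to 100 and modified = correct + type1", {
  set.seed(51)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    td <- sample(DIRECTIONS, n, replace = TRUE)
    ed <- sample(DIRECTIONS, n, replace = TRUE)
    sm <- session_metrics(td, ed)
    expect_equal(sm$accuracy_pct + sm$type1_pct + sm$type2_pct +
                   sm$type3_pct + sm$type4_pct, 100, tolerance = 1e-9)
    expect_equal(sm$modified_accuracy_pct, sm$accuracy_pct + sm$type1_pct)
    expect_equal(sum(sm$confusion), n)
    expect_equal(as.numeric(rowSums(sm$confusion)),
                 as.numeric(table(factor(td, levels = DIRECTIONS))[DIRECTIONS]))
  }
  all_ok <- session_metrics(rep("NE", 10), rep("NE", 10))
  expect_equal(all_ok$accuracy_pct, 100)
  expect_equal(all_ok$type4_pct, 0)
})

test_that("headline accuracy arithmetic: 48.6 + 33.4 gives modified 82.0", {
  # integer confusion counts approximating the reported rates on 160 trials
  td <- rep(DIRECTIONS, each = 20)
  ed <- td
  flip <- function(d, k) DIRECTIONS[(direction_index(d) + k) %% 8 + 1]
  idx_t1 <- 1:53; idx_t2 <- 54:72; idx_t3 <- 73:78; idx_t4 <- 79:82
  ed[idx_t1] <- sapply(td[idx_t1], flip, k = 1)
  ed[idx_t2] <- sapply(td[idx_t2], flip, k = 2)
  ed[idx_t3] <- sapply(td[idx_t3], flip, k = 3)
  ed[idx_t4] <- sapply(td[idx_t4], flip, k = 4)
  sm <- session_metrics(td, ed)
  expect_equal(sm$accuracy_pct, 48.75)
  expect_equal(sm$type1_pct, 33.125)
  expect_equal(sm$modified_accuracy_pct, sm$accuracy_pct + sm$type1_pct)
  expect_equal(sm$modified_accuracy_pct, 81.875)
})

test_that("polar transform matches hand-worked points and round-trips", {
  expect_equal(to_polar(c(1, 0)), list(rho = 1, theta_deg = 0, theta_undefined = FALSE))
  expect_equal(to_polar(c(0, 1))$theta_deg, 90)
  expect_equal(to_polar(c(-1, 0))$theta_deg, 180)
  expect_true(to_polar(c(0, 0))$theta_undefined)
  set.seed(52)
  for (i in 1:1000) {
    p <- rnorm(2)
    pol <- to_polar(p)
    back <- pol$rho * c(cos(pol$theta_deg * pi / 180), sin(pol$theta_deg * pi / 180))
    expect_equal(back, p, tolerance = 1e-12)
  }
})

test_that("repeatability errors use absolute wrapped differences", {
  same <- repeatability_errors(c(0.25, 0), c(0.25, 0))
  expect_equal(same$delta_rho_m, 0)
  expect_equal(same$delta_theta_deg, 0)
  r <- repeatability_errors(0.27 * c(cos(5 * pi / 180), sin(5 * pi / 180)),
                            c(0.25, 0))
  expect_equal(r$delta_rho_m, 0.02, tolerance = 1e-12)
  expect_equal(r$delta_theta_deg, 5, tolerance = 1e-12)
  # wrap across 0/360
  w <- repeatability_errors(c(cos(359 * pi / 180), sin(359 * pi / 180)),
                            c(cos(1 * pi / 180), sin(1 * pi / 180)))
  expect_equal(w$delta_theta_deg, 2, tolerance = 1e-9)
  expect_true(repeatability_errors(c(0, 0), c(0.25, 0))$excluded)
})

test_that("iEMG normalization fixes the scale", {
  mvc <- setNames(rep(2, 6), default_muscles())
  z <- envelope_series(matrix(0, 6, 101, dimnames = list(default_muscles(), NULL)), 100)
  expect_equal(unname(iemg(z, mvc)), rep(0, 6))
  cst <- envelope_series(matrix(2, 6, 101, dimnames = list(default_muscles(), NULL)), 100)
  expect_equal(unname(iemg(cst, mvc)), rep(100, 6), tolerance = 1e-9)
  ramp <- envelope_series(matrix(rep(seq(0, 2, length.out = 101), each = 6), 6,
                                 dimnames = list(default_muscles(), NULL)), 100)
  expect_equal(unname(iemg(ramp, mvc)), rep(50, 6), tolerance = 0.5)
  expect_error(iemg(cst, NULL), "MVC")
})

test_that("movement end finds the 20 percent decay point", {
  t <- seq(0, 1, by = 0.001)
  tri <- ifelse(t <= 0.5, 2 * t, 2 * (1 - t))
  me <- movement_end(tri)
  expect_equal(t[me$index], 0.9, tolerance = 0.001)
  expect_true(me$reached_threshold)
  # Gaussian bump vs a literal scan
  g <- exp(-(t - 0.4)^2 / (2 * 0.1^2))
  me2 <- movement_end(g)
  pk <- which.max(g)
  scan <- pk + which(g[(pk + 1):length(g)] <= 0.2 * max(g))[1]
  expect_equal(me2$index, scan)
  rising <- movement_end(t)
  expect_equal(rising$index, length(t))
  expect_false(rising$reached_threshold)
  expect_error(movement_end(rep(0, 10)), "peak")
})

test_that("kinematic benchmark bins angles every 45 degrees", {
  expect_equal(kinematic_benchmark(matrix(c(0, 0.1), 1))[1], "N")
  expect_equal(kinematic_benchmark(matrix(c(0.1, 0), 1))[1], "E")
  # exact bin edge 67.5 deg: tie between NE and N goes to NE (lower index)
  edge <- 0.1 * c(cos(67.5 * pi / 180), sin(67.5 * pi / 180))
  expect_equal(kinematic_benchmark(matrix(edge, 1))[1], "NE")
  # below the displacement gate the previous estimate is inherited, from "E"
  traj <- rbind(c(0.001, 0), c(0.002, 0.002), c(0, 0.05), c(0.001, 0))
  expect_equal(kinematic_benchmark(traj), c("E", "E", "N", "N"))
})

test_that("benchmark agrees with a brute-force angle-bin oracle", {
  set.seed(53)
  pts <- matrix(rnorm(2e4, 0, 0.2), ncol = 2)
  est <- kinematic_benchmark(pts, min_disp = 0)
  th <- atan2(pts[, 2], pts[, 1]) * 180 / pi %% 360
  for (i in sample(nrow(pts), 500)) {
    diffs <- abs(((th[i] - DIRECTION_ANGLES_DEG + 180) %% 360) - 180)
    expect_equal(est[i], DIRECTIONS[which.min(diffs)])
  }
})

test_that("adjusted chance level reproduces the exact binomial rule", {
  expect_equal(adjusted_chance_level(160, 8), 18.125)
  # direct enumeration oracle for all n up to 30
  for (n in 1:30) {
    cdf <- cumsum(dbinom(0:n, n, 1 / 8))
    k <- which(cdf >= 0.975)[1] - 1
    expect_equal(adjusted_chance_level(n, 8), 100 * k / n)
  }
  # approaches the nominal rate for large n
  expect_lt(adjusted_chance_level(1e6, 8), 12.6)
  expect_gt(adjusted_chance_level(1e6, 8), 12.5)
  # monotone: more trials lower the bar, more classes lower it too
  ns <- c(20, 40, 80, 160, 320)
  expect_true(all(diff(sapply(ns, adjusted_chance_level, n_classes = 8)) < 0))
  expect_gt(adjusted_chance_level(160, 4), adjusted_chance_level(160, 8))
})

test_that("accuracy-vs-time curve is consistent with final session metrics", {
  est1 <- c(rep("W", 30), rep("N", 30))   # converges to correct
  est2 <- rep("S", 60)                    # stays opposite
  curve <- accuracy_vs_time(list(est1, est2), c("N", "N"), from_s = 0.05)
  expect_equal(nrow(curve), 56)
  expect_equal(curve$modified_accuracy_pct[curve$time_s == 0.1], 0)
  expect_equal(curve$modified_accuracy_pct[curve$time_s == 0.6], 50)
  sm <- session_metrics(c("N", "N"), c(est1[60], est2[60]))
  expect_equal(curve$modified_accuracy_pct[56], sm$modified_accuracy_pct)
  flat <- accuracy_vs_time(list(rep("NE", 60)), "NE")
  expect_true(all(flat$modified_accuracy_pct == 100))
})
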