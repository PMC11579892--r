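arm <- arm_model(l_upper_m = 0.3, l_forearm_m = 0.35)

test_that("reference poses land where geometry says", {
  expect_equal(forward_kinematics(c(0, 0, 0, 0), arm), c(0, 0, -0.65))
  expect_equal(forward_kinematics(c(0, 0, 0, pi / 2), arm), c(0.35, 0, -0.3),
               tolerance = 1e-12)
  # shoulder flexion 90 deg: whole arm horizontal along +x
  expect_equal(forward_kinematics(c(0, pi / 2, 0, 0), arm), c(0.65, 0, 0),
               tolerance = 1e-12)
})

test_that("forward kinematics matches an independent homogeneous-transform chain", {
  set.seed(41)
  for (i in 1:50) {
    q <- runif(4, -pi, pi)
    expect_equal(forward_kinematics(q, arm),
                 oracle_fk_homogeneous(q, 0.3, 0.35), tolerance = 1e-12)
  }
})

test_that("jacobian agrees with central finite differences at random poses", {
  set.seed(42)
  hstep <- 1e-6
  worst <- 0
  for (i in 1:100) {
    q <- runif(4, -pi, pi)
    J <- jacobian(q, arm)
    Jfd <- vapply(1:4, function(j) {
      dq <- rep(0, 4); dq[j] <- hstep
      (forward_kinematics(q + dq, arm) - forward_kinematics(q - dq, arm)) / (2 * hstep)
    }, numeric(3))
    worst <- max(worst, max(abs(J - Jfd)))
  }
  expect_lt(worst, 1e-6)
})

test_that("structural jacobian columns behave as geometry dictates", {
  # extended arm: internal rotation axis is parallel to the hand offset
  expect_lt(max(abs(jacobian(c(0, 0, 0, 0), arm)[, 3])), 1e-12)
  # elbow column magnitude equals the forearm lever arm
  J <- jacobian(c(0, 0, 0, pi / 3), arm)
  expect_equal(sqrt(sum(J[, 4]^2)), 0.35, tolerance = 1e-12)
})

test_that("virtual force follows the stiffness law", {
  g <- c(0.01, 0.03, 0.01)
  expect_equal(virtual_force(c(1, 2, 3), c(1, 2, 3), g, arm), c(0, 0, 0))
  expect_equal(virtual_force(c(0, 0, 0), c(1, 1, 1), g, arm), g)
  F1 <- virtual_force(c(0, 0, 0), c(0.1, 0.2, -0.1), g, arm)
  F2 <- virtual_force(c(0, 0, 0), c(0.2, 0.4, -0.2), g, arm)
  expect_equal(F2, 2 * F1)
  # rotation into the sAA frame
  Rb <- rot_z_90 <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  arm_r <- arm_model(base_rotation = Rb)
  expect_equal(virtual_force(c(0, 0, 0), c(1, 0, 0), c(1, 1, 1), arm_r),
               as.numeric(Rb %*% c(1, 0, 0)))
})

test_that("statics torques satisfy the virtual-work identity", {
  set.seed(43)
  for (i in 1:100) {
    q <- runif(4, -pi, pi)
    F <- rnorm(3)
    tau <- assistive_torques(F, q, arm)
    dq <- rnorm(4) * 1e-5
    expect_equal(sum(tau * dq), sum(F * (jacobian(q, arm) %*% dq)),
                 tolerance = 1e-9)
  }
  expect_equal(assistive_torques(c(0, 0, 0), c(0.3, 0.2, 0.1, 0.5), arm), rep(0, 4))
})

test_that("gravity torques vanish for massless or hanging configurations", {
  arm0 <- arm_model(masses_kg = c(0, 0))
  expect_equal(gravity_torques(c(0.4, 0.8, 0.2, 1), arm0), rep(0, 4))
  expect_equal(gravity_torques(c(0, 0, 0, 0), arm), rep(0, 4), tolerance = 1e-12)
})

test_that("horizontal upper arm needs m g c of shoulder-flexion torque", {
  a <- arm_model(l_upper_m = 0.3, l_forearm_m = 0.35,
                 masses_kg = c(2, 0), centers_m = c(0.13, 0.16))
  tau <- gravity_torques(c(0, pi / 2, 0, 0), a, g = 9.81)
  expect_equal(tau[2], 2 * 9.81 * 0.13, tolerance = 1e-9)
})

test_that("tau_ref decomposes into gravity plus assistance", {
  q <- c(0.2, 0.5, -0.1, 0.9)
  F <- c(1, -2, 0.5)
  tc <- reference_torques(F, q, arm)
  expect_equal(tc$tau_ref, tc$tau_gravity + tc$tau_assist)
})

test_that("manipulability is zero at the extended singular pose and in [0,1]", {
  expect_lt(manipulability(c(0, 0, 0, 0), arm), 1e-9)
  set.seed(44)
  for (i in 1:1000) {
    w <- manipulability(runif(4, -pi, pi), arm)
    expect_true(w >= 0 && w <= 1)
  }
  # isotropic jacobian: equal singular values give exactly 1 (identity chain)
  ident_J <- diag(3)
  ev <- eigen(ident_J %*% t(ident_J), only.values = TRUE)$values
  expect_equal(sqrt(min(ev) / max(ev)), 1)
})

test_that("yoshikawa variant is bounded and vanishes at singularities", {
  expect_lt(manipulability(c(0, 0, 0, 0), arm, measure = "yoshikawa_norm"), 1e-9)
  set.seed(45)
  for (i in 1:50) {
    w <- manipulability(runif(4, -1.5, 1.5), arm, measure = "yoshikawa_norm")
    expect_true(w >= 0 && w <= 1)
  }
})

test_that("manipulability varies continuously along a trajectory", {
  qs <- t(sapply(seq(0.1, 1.4, length.out = 50), function(a) c(0.1, a, 0.05, 1.2 - a / 2)))
  ws <- apply(qs, 1, manipulability, arm = arm)
  expect_lt(max(abs(diff(ws))), 0.05)
  expect_equal(trajectory_manipulability(qs, arm), mean(ws))
})

test_that("inverse kinematics reaches targets inside the workspace", {
  set.seed(46)
  for (i in 1:10) {
    q_true <- runif(4, c(-0.5, 0, -0.5, 0.2), c(0.5, 1.2, 0.5, 1.5))
    x <- forward_kinematics(q_true, arm)
    q <- inverse_kinematics(x, arm)
    expect_lt(sqrt(sum((forward_kinematics(q, arm) - x)^2)), 1e-4)
  }
})

test_that("assisted-reach simulation integrates intent exactly at zero admittance", {
  set.seed(47)
  v <- matrix(rnorm(60 * 3, 0, 0.1), 60, 3)
  X <- simulate_assisted_reach(v, c(0, 0, 0), c(0.25, 0, 0),
                               gains = c(0.01, 0.03, 0.01), admittance = 0,
                               arm = arm, dt = 0.01)
  expect_equal(X[61, ], colSums(v) * 0.01, tolerance = 1e-12)
})

test_that("with zero intent the hand converges monotonically to the target", {
  v <- matrix(0, 400, 3)
  X <- simulate_assisted_reach(v, c(0, 0, 0), c(0.2, 0.15, 0),
                               gains = c(0.01, 0.03, 0.01), admittance = 1,
                               arm = arm, dt = 0.01, gain_multiplier = 1000)
  d <- sqrt(rowSums(sweep(X, 2, c(0.2, 0.15, 0))^2))
  expect_true(all(diff(d) <= 1e-12))
  expect_lt(d[401], 0.01)
})

test_that("a correct estimate plus default assistance ends within 1 cm of target", {
  tgt <- c(0.25 * cos(pi / 4), 0.25 * sin(pi / 4), 0)
  mj <- min_jerk(c(0, 0, 0), tgt, 1.2, 100)
  X <- simulate_assisted_reach(mj$velocity[-1, ], c(0, 0, 0), tgt,
                               gains = c(0.01, 0.03, 0.01), admittance = 1,
                               arm = arm, dt = 0.01, gain_multiplier = 1000)
  expect_lt(sqrt(sum((X[nrow(X), ] - tgt)^2)), 0.01)
})

test_that("misassistance error grows with admittance", {
  tgt <- c(0.25, 0, 0)
  wrong <- c(-0.25, 0, 0)  # opposite-direction misestimate
  mj <- min_jerk(c(0, 0, 0), tgt, 1.2, 100)
  errs <- sapply(c(0, 0.5, 1), function(adm) {
    X <- simulate_assisted_reach(mj$velocity[-1, ], c(0, 0, 0), wrong,
                                 gains = c(0.01, 0.03, 0.01), admittance = adm,
                                 arm = arm, dt = 0.01, gain_multiplier = 1000)
    sqrt(sum((X[nrow(X), ] - tgt)^2))
  })
  expect_true(all(diff(errs) > 0))
})
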