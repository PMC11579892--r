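#' Simplified 4-DOF exoskeleton arm model
#'
#' A generic serial chain with three intersecting shoulder rotations —
#' abduction/adduction (sAA, about +x), flexion/extension (sFE, about -y, so
#' positive flexion brings the arm forward along +x) and internal/external
#' rotation (sIE, about the humerus axis) — followed by elbow
#' flexion/extension (eFE, about -y of the forearm frame). In the reference
#' pose (all angles zero) the arm hangs straight down: the hand sits at
#' (0, 0, -(l_upper + l_forearm)) in the shoulder frame. Point masses at
#' fixed distances along each segment provide a generic gravity term.
#'
#' @param l_upper_m,l_forearm_m segment lengths in meters (forearm includes
#'   the hand).
#' @param masses_kg point masses of the two segments.
#' @param centers_m mass-center distances from each segment's proximal joint.
#' @param base_rotation 3x3 rotation from the global frame to the shoulder
#'   (sAA) frame; identity by default.
#' @param joint_limits 2x4 matrix of per-joint angle bounds in radians.
#' @return an object of class `arm_model`.
#' @export
arm_model <- function(l_upper_m = 0.30, l_forearm_m = 0.35,
                      masses_kg = c(2.0, 1.5),
                      centers_m = c(0.13, 0.16),
                      base_rotation = diag(3),
                      joint_limits = rbind(rep(-pi, 4), rep(pi, 4))) {
  stopifnot(l_upper_m > 0, l_forearm_m > 0, all(masses_kg >= 0))
  if (max(abs(crossprod(base_rotation) - diag(3))) > 1e-9)
    stop("base_rotation must be orthonormal")
  structure(list(l_upper_m = l_upper_m, l_forearm_m = l_forearm_m,
                 masses_kg = masses_kg, centers_m = centers_m,
                 base_rotation = base_rotation, joint_limits = joint_limits,
                 joint_names = c("sAA", "sFE", "sIE", "eFE")),
            class = "arm_model")
}

rot_x <- function(t) rbind(c(1, 0, 0), c(0, cos(t), -sin(t)), c(0, sin(t), cos(t)))
rot_y <- function(t) rbind(c(cos(t), 0, sin(t)), c(0, 1, 0), c(-sin(t), 0, cos(t)))
rot_z <- function(t) rbind(c(cos(t), -sin(t), 0), c(sin(t), cos(t), 0), c(0, 0, 1))

# Joint axes (global), joint origins, elbow/hand positions for pose q.
arm_frames <- function(q, arm) {
  R1 <- rot_x(q[1])                 # sAA
  R2 <- R1 %*% rot_y(-q[2])         # sFE (positive = forward flexion)
  R3 <- R2 %*% rot_z(q[3])          # sIE about humerus long axis
  p_elbow <- R3 %*% c(0, 0, -arm$l_upper_m)
  R4 <- R3 %*% rot_y(-q[4])         # eFE
  p_hand <- p_elbow + R4 %*% c(0, 0, -arm$l_forearm_m)
  axes <- cbind(c(1, 0, 0),         # sAA axis, global x
                R1 %*% c(0, -1, 0), # sFE axis
                R2 %*% c(0, 0, 1),  # sIE axis (humerus z before rotation)
                R3 %*% c(0, -1, 0)) # eFE axis
  origins <- cbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0), p_elbow)
  list(axes = axes, origins = origins, p_elbow = as.numeric(p_elbow),
       p_hand = as.numeric(p_hand), R3 = R3, R4 = R4)
}

#' Forward kinematics: hand position for a joint configuration
#'
#' @param q 4 joint angles in radians (sAA, sFE, sIE, eFE).
#' @param arm an `arm_model`.
#' @return hand position 3-vector in the shoulder (sAA) frame.
#' @export
forward_kinematics <- function(q, arm) {
  stopifnot(length(q) == 4, all(is.finite(q)))
  arm_frames(q, arm)$p_hand
}

#' Geometric Jacobian of the hand position
#'
#' Column i is axis_i x (p_hand - origin_i) for each revolute joint.
#'
#' @inheritParams forward_kinematics
#' @return 3x4 matrix d(hand position)/dq.
#' @export
jacobian <- function(q, arm) {
  f <- arm_frames(q, arm)
  J <- matrix(0, 3, 4)
  for (i in 1:4) {
    J[, i] <- pracma::cross(f$axes[, i], f$p_hand - f$origins[, i])
  }
  colnames(J) <- arm$joint_names
  J
}

#' Virtual-stiffness assistive force
#'
#' Element-wise stiffness gains times the displacement from the hand to the
#' target, expressed in the sAA frame through the base rotation: the force
#' field that attracts the hand toward the estimated target.
#'
#' @param x_hand,x_target 3-vectors in the global frame.
#' @param gains per-axis stiffness 3-vector (force per unit displacement).
#' @param arm an `arm_model` (supplies the global-to-sAA rotation).
#' @param gain_multiplier scalar applied to `gains` (default 1; the
#'   simulator uses a larger value so assistance is mechanically meaningful).
#' @return force 3-vector in the sAA frame.
#' @export
virtual_force <- function(x_hand, x_target, gains, arm, gain_multiplier = 1) {
  stopifnot(all(gains >= 0))
  as.numeric(arm$base_rotation %*% (gain_multiplier * gains * (x_target - x_hand)))
}

#' Assistive joint torques from a hand force (statics)
#'
#' tau = J^T F: the joint torques statically equivalent to applying force F
#' at the hand.
#'
#' @param F force 3-vector in the frame the Jacobian is expressed in.
#' @inheritParams forward_kinematics
#' @return torque 4-vector in N m.
#' @export
assistive_torques <- function(F, q, arm) {
  as.numeric(t(jacobian(q, arm)) %*% F)
}

#' Gravity-compensation torques for the point-mass segment model
#'
#' Torques that exactly cancel gravity acting on the two point masses:
#' tau_g = -sum_i J_ci^T (0, 0, -m_i g), with J_ci the Jacobian of mass
#' center i. Zero for a massless configuration and in any pose where all
#' mass centers hang on the joint axes' plane of action.
#'
#' @inheritParams forward_kinematics
#' @param g gravitational acceleration (m/s^2).
#' @return torque 4-vector in N m.
#' @export
gravity_torques <- function(q, arm, g = 9.81) {
  f <- arm_frames(q, arm)
  c1 <- as.numeric(f$R3 %*% c(0, 0, -arm$centers_m[1]))
  c2 <- f$p_elbow + as.numeric(f$R4 %*% c(0, 0, -arm$centers_m[2]))
  tau <- numeric(4)
  for (i in 1:4) {
    J1 <- pracma::cross(f$axes[, i], c1 - f$origins[, i])
    J2 <- pracma::cross(f$axes[, i], c2 - f$origins[, i])
    # upper-arm mass is not moved by the elbow joint
    w1 <- if (i < 4) arm$masses_kg[1] else 0
    tau[i] <- -(w1 * J1[3] + arm$masses_kg[2] * J2[3]) * (-g)
  }
  tau
}

#' Reference torque command: gravity compensation plus assistance
#'
#' @param F assistive hand force 3-vector (sAA frame).
#' @inheritParams forward_kinematics
#' @return list with `tau_assist`, `tau_gravity` and `tau_ref`
#'   (element-wise sum), each a 4-vector.
#' @export
reference_torques <- function(F, q, arm) {
  ta <- assistive_torques(F, q, arm)
  tg <- gravity_torques(q, arm)
  list(tau_assist = ta, tau_gravity = tg, tau_ref = tg + ta)
}

#' Manipulability index of a configuration
#'
#' Default measure: sqrt(lambda_min / lambda_max) of J J^T — the inverse
#' condition number of the Jacobian. It is bounded in [0, 1] and equals 0
#' exactly at singular configurations, where small end-effector velocities
#' require large joint velocities. A Yoshikawa-style alternative,
#' sqrt(det(J J^T)) normalized by a supplied workspace maximum, is
#' selectable.
#'
#' @inheritParams forward_kinematics
#' @param measure "inv_cond" (default) or "yoshikawa_norm".
#' @param yoshikawa_max normalization constant for the Yoshikawa measure.
#' @return scalar in [0, 1].
#' @export
manipulability <- function(q, arm, measure = c("inv_cond", "yoshikawa_norm"),
                           yoshikawa_max = NULL) {
  measure <- match.arg(measure)
  J <- jacobian(q, arm)
  ev <- eigen(J %*% t(J), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  if (max(ev) == 0) stop("undefined configuration: Jacobian is identically zero")
  if (measure == "inv_cond") return(sqrt(min(ev) / max(ev)))
  w <- sqrt(prod(ev))
  if (is.null(yoshikawa_max)) {
    yoshikawa_max <- yoshikawa_workspace_max(arm)
  }
  min(w / yoshikawa_max, 1)
}

# Max Yoshikawa measure over a coarse deterministic pose grid (cached per call).
yoshikawa_workspace_max <- function(arm, n_grid = 7) {
  gr <- seq(-pi / 2, pi / 2, length.out = n_grid)
  best <- 0
  for (q2 in gr) for (q4 in gr) {
    J <- jacobian(c(0, q2, 0, q4), arm)
    ev <- pmax(eigen(J %*% t(J), symmetric = TRUE, only.values = TRUE)$values, 0)
    best <- max(best, sqrt(prod(ev)))
  }
  best
}

#' Mean manipulability along a joint trajectory
#'
#' The per-movement index: the mean of per-sample manipulability values over
#' the time-normalized trajectory.
#'
#' @param Q matrix of joint configurations, samples x 4.
#' @inheritParams manipulability
#' @return scalar in [0, 1].
#' @export
trajectory_manipulability <- function(Q, arm, measure = "inv_cond") {
  mean(apply(Q, 1, manipulability, arm = arm, measure = measure))
}

#' Inverse kinematics by damped least squares
#'
#' Iteratively moves a seed configuration toward a hand target using the
#' damped pseudo-inverse of the Jacobian, clamping to joint limits. Needed
#' only by the synthetic generator to turn hand trajectories into joint
#' trajectories for manipulability evaluation.
#'
#' @param x_target hand position 3-vector (shoulder frame).
#' @param arm an `arm_model`.
#' @param q0 starting configuration.
#' @param damping damped-least-squares regularization.
#' @param max_iter,tol iteration cap and position tolerance in meters.
#' @return joint 4-vector.
#' @export
inverse_kinematics <- function(x_target, arm, q0 = c(0.2, 0.5, 0, 0.8),
                               damping = 1e-3, max_iter = 200, tol = 1e-6) {
  q <- q0
  for (it in seq_len(max_iter)) {
    e <- x_target - forward_kinematics(q, arm)
    if (sqrt(sum(e^2)) < tol) break
    J <- jacobian(q, arm)
    dq <- as.numeric(t(J) %*% solve(J %*% t(J) + damping^2 * diag(3), e))
    q <- pmin(pmax(q + dq, arm$joint_limits[1, ]), arm$joint_limits[2, ])
  }
  q
}

#' Simulate an assisted reach in hand space
#'
#' First-order closed-loop stand-in exercising the virtual-stiffness statics
#' end to end: x[k+1] = x[k] + (v_intent[k] + admittance * F_v[k]) * dt,
#' where F_v is the stiffness force toward the (possibly misestimated)
#' target. With zero admittance the trajectory is the pure integrated
#' intent. Stable per axis whenever admittance * gain * dt < 2.
#'
#' @param v_intent matrix of intended hand velocities, samples x 3 (m/s).
#' @param x_start starting hand position 3-vector.
#' @param x_target assistance attraction point 3-vector.
#' @param gains stiffness 3-vector; multiplied by `gain_multiplier`.
#' @param admittance velocity produced per unit force (m/s per N).
#' @param arm an `arm_model`.
#' @param dt control period in seconds.
#' @param gain_multiplier see [virtual_force()] (default 1000, treating the
#'   printed per-millimeter gains as per-meter).
#' @return matrix of hand positions, (samples + 1) x 3, starting at `x_start`.
#' @export
simulate_assisted_reach <- function(v_intent, x_start, x_target, gains,
                                    admittance, arm, dt = 0.01,
                                    gain_multiplier = 1000) {
  stopifnot(admittance >= 0, ncol(v_intent) == 3)
  n <- nrow(v_intent)
  X <- matrix(NA_real_, n + 1, 3)
  X[1, ] <- x_start
  Rb <- t(arm$base_rotation)  # force back to global for integration
  for (k in seq_len(n)) {
    Fv <- virtual_force(X[k, ], x_target, gains, arm, gain_multiplier)
    X[k + 1, ] <- X[k, ] + (v_intent[k, ] + admittance * as.numeric(Rb %*% Fv)) * dt
  }
  X
}
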