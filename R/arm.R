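#' The 22-degree-of-freedom arm/hand state
#'
#' Joint layout (all angles rad): 1-3 shoulder (rotations about the x, y, z
#' axes, composed as `Rz(t3) Ry(t2) Rx(t1)`), 4 elbow hinge (about the local
#' x axis), 5-7 wrist ball joint (`wr_x, wr_y, wr_z`), 8-19 four fingers
#' (index, middle, ring, pinky) with three flexion hinges each
#' (MCP, PIP, DIP), 20-22 thumb (base abduction, base flexion, MCP flexion).
#' At rest the upper arm points along -y and the forearm along -z; limb
#' lengths default to macaque proportions for a 7.5 kg animal.
#'
#' @param cfg an [ag_config()] list (geometry and joint limits).
#' @param theta numeric 22-vector of joint angles (rad).
#' @param thetadot numeric 22-vector of joint velocities (rad/s).
#' @return an object of class `"arm_hand_state"`.
#' @export
arm_hand_state <- function(cfg, theta = rep(0, 22), thetadot = rep(0, 22)) {
  theta <- as.numeric(theta); thetadot <- as.numeric(thetadot)
  if (length(theta) != 22 || length(thetadot) != 22) {
    stop("arm/hand state needs exactly 22 joint angles and velocities",
         call. = FALSE)
  }
  lim <- joint_limits(cfg)
  if (any(theta < lim[, 1] - 1e-9 | theta > lim[, 2] + 1e-9)) {
    stop("joint angle outside its configured limits", call. = FALSE)
  }
  structure(list(theta = theta, thetadot = thetadot,
                 l1 = cfg$arm$l1, l2 = cfg$arm$l2, arm = cfg$arm,
                 limits = lim),
            class = "arm_hand_state")
}

#' Joint limit matrix
#' @param cfg an [ag_config()] list.
#' @return 22 x 2 matrix of (lower, upper) bounds (rad).
#' @export
joint_limits <- function(cfg) {
  a <- cfg$arm
  lim <- rbind(
    matrix(rep(a$shoulder_lim, 3), ncol = 2, byrow = TRUE),
    a$elbow_lim,
    matrix(rep(a$wrist_lim, 3), ncol = 2, byrow = TRUE),
    matrix(rep(a$finger_lim, 12), ncol = 2, byrow = TRUE),
    a$thumb_ab_lim,
    matrix(rep(a$finger_lim, 2), ncol = 2, byrow = TRUE))
  dimnames(lim) <- list(dof_names(), c("lower", "upper"))
  lim
}

dof_names <- function() {
  c("sh_x", "sh_y", "sh_z", "elbow", "wr_x", "wr_y", "wr_z",
    paste0(rep(c("index", "middle", "ring", "pinky"), each = 3),
           c("_mcp", "_pip", "_dip")),
    "thumb_ab", "thumb_flex", "thumb_mcp")
}

shoulder_rotation <- function(theta) {
  rot_z(theta[3]) %*% rot_y(theta[2]) %*% rot_x(theta[1])
}

#' Forward kinematics of the arm and hand
#'
#' Composes the shoulder and elbow rotations over the `l1`, `l2` segments to
#' place the wrist, then chains the wrist ball joint and finger/thumb hinges
#' over the configured hand segment lengths to place every contact landmark.
#'
#' @param state an [arm_hand_state()].
#' @param check_limits error if any angle is outside its limit interval.
#' @return list with `wrist`, `elbow` (3-vectors), `R_hand` (3x3 hand frame),
#'   and `landmarks`: a 3 x 14 matrix with columns `palm`,
#'   `finger_pad_1..4`, `finger_side_1..4`, `inner_1..4` (PIP joints),
#'   `thumb_pad`, `thumb_side` — wait, 15 columns; see `colnames`.
#' @export
forward_kinematics <- function(state, check_limits = TRUE) {
  th <- state$theta
  if (check_limits &&
      any(th < state$limits[, 1] - 1e-9 | th > state$limits[, 2] + 1e-9)) {
    stop("joint angle outside its configured limits", call. = FALSE)
  }
  a <- state$arm
  R_sh <- shoulder_rotation(th)
  elbow <- R_sh %*% c(0, -state$l1, 0)
  R_el <- R_sh %*% rot_x(th[4])
  wrist <- elbow + R_el %*% c(0, 0, -state$l2)
  R_hand <- R_el %*% rot_z(th[7]) %*% rot_y(th[6]) %*% rot_x(th[5])

  world <- wrist[, 1] + R_hand %*% hand_landmarks_local(th, a)
  colnames(world) <- landmark_names
  list(wrist = wrist[, 1], elbow = elbow[, 1], R_hand = R_hand,
       landmarks = world)
}

landmark_names <- c(
  "palm",
  "finger_pad_1", "finger_side_1", "inner_1",
  "finger_pad_2", "finger_side_2", "inner_2",
  "finger_pad_3", "finger_side_3", "inner_3",
  "finger_pad_4", "finger_side_4", "inner_4",
  "thumb_pad", "thumb_side")

# body-part group per landmark column (opposition classes)
landmark_groups <- c("palm", rep(c("finger", "finger", "finger"), 4),
                     "thumb", "thumb")

# hand-frame landmark positions (3 x 15), allocation-lean for the trial loop.
# Hand frame: x radial (thumb side), y palmar (palm normal), z proximal;
# fingers flex from the distal -z direction toward +y.
hand_landmarks_local <- function(th, a) {
  segs <- a$finger_segments
  lm <- matrix(0, 3, 15)
  lm[, 1] <- c(0, 0.010, -a$palm_length * 0.6)  # palm patch
  for (i in 1:4) {
    j <- 7 + (i - 1) * 3
    c1 <- th[j + 1]; c2 <- c1 + th[j + 2]; c3 <- c2 + th[j + 3]
    bx <- a$finger_spread[i]
    # chained flexion in the (distal, palmar) plane
    y1 <- segs[1] * sin(c1); z1 <- -a$palm_length - segs[1] * cos(c1)
    y2 <- y1 + segs[2] * sin(c2); z2 <- z1 - segs[2] * cos(c2)
    y3 <- y2 + segs[3] * sin(c3); z3 <- z2 - segs[3] * cos(c3)
    col <- 2 + (i - 1) * 3
    lm[, col] <- c(bx, y3, z3)                       # finger pad (tip)
    lm[, col + 1] <- c(bx + 0.005, (y1 + y2) / 2, (z1 + z2) / 2)  # radial side
    lm[, col + 2] <- c(bx, y1, z1)                   # inner (PIP joint)
  }
  ab <- th[20]; fl <- th[21]; fl2 <- fl + th[22]
  v1 <- c(cos(ab) * cos(fl), sin(ab) * cos(fl), -sin(fl))
  v2 <- c(cos(ab) * cos(fl2), sin(ab) * cos(fl2), -sin(fl2))
  tmcp <- a$thumb_base + a$thumb_segments[1] * v1
  lm[, 14] <- tmcp + a$thumb_segments[2] * v2        # thumb pad
  lm[, 15] <- tmcp                                   # thumb side
  lm
}

#' Analytic arm Jacobian
#'
#' The 3 x 4 matrix of partial derivatives of wrist position with respect to
#' the three shoulder angles and the elbow angle, built from exact derivative
#' rotation matrices (it is the differential of [forward_kinematics()]).
#'
#' @param state an [arm_hand_state()].
#' @return 3 x 4 numeric matrix (m/rad).
#' @export
jacobian <- function(state) {
  th <- state$theta
  if (any(!is.finite(th[1:4]))) stop("non-finite joint angles", call. = FALSE)
  a1 <- c(0, -state$l1, 0); a2 <- c(0, 0, -state$l2)
  Rx1 <- rot_x(th[1]); Ry2 <- rot_y(th[2]); Rz3 <- rot_z(th[3])
  Rx4 <- rot_x(th[4])
  v <- a1 + Rx4 %*% a2
  J <- cbind(
    Rz3 %*% Ry2 %*% drot_x(th[1]) %*% v,
    Rz3 %*% drot_y(th[2]) %*% Rx1 %*% v,
    drot_z(th[3]) %*% Ry2 %*% Rx1 %*% v,
    Rz3 %*% Ry2 %*% Rx1 %*% drot_x(th[4]) %*% a2)
  unname(J)
}

#' Moore-Penrose pseudo-inverse of the arm Jacobian
#'
#' `J+ = J^T (J J^T)^(-1)`; errors with class `"affgrasp_singularity"` when
#' `J J^T` is ill-conditioned (outstretched-arm singularity).
#'
#' @param J 3 x 4 Jacobian.
#' @param cond_cap condition-number cap on `J J^T`.
#' @return 4 x 3 matrix.
#' @export
jacobian_pseudoinverse <- function(J, cond_cap = 1e8) {
  JJt <- J %*% t(J)
  if (!all(is.finite(JJt)) || rcond(JJt) < 1 / cond_cap) {
    stop(structure(class = c("affgrasp_singularity", "error", "condition"),
                   list(message = "Jacobian is rank deficient (kinematic singularity)",
                        call = sys.call())))
  }
  t(J) %*% solve(JJt)
}

#' One inverse-kinematics step
#'
#' Maps a desired small wrist displacement to target shoulder/elbow angles via
#' the Jacobian pseudo-inverse: `theta_hat = theta + J+ d`.  Displacements
#' above the per-step cap are scaled down to it; targets outside the joint
#' limits are clamped.  Both conditions are flagged in the result.
#'
#' @param state an [arm_hand_state()].
#' @param displacement desired wrist displacement, 3-vector (m).
#' @return list(`theta_hat` 4-vector, `clamped`, `capped` logicals).
#' @export
ik_step <- function(state, displacement) {
  d <- as.numeric(displacement)
  cap <- state$arm$ik_step_cap
  nrm <- sqrt(sum(d^2))
  capped <- FALSE
  if (nrm > cap) { d <- d * (cap / nrm); capped <- TRUE }
  Jp <- jacobian_pseudoinverse(jacobian(state), state$arm$cond_cap)
  th_hat <- state$theta[1:4] + as.numeric(Jp %*% d)
  lim <- state$limits[1:4, , drop = FALSE]
  clamped <- any(th_hat < lim[, 1] | th_hat > lim[, 2])
  th_hat <- pmin(pmax(th_hat, lim[, 1]), lim[, 2])
  list(theta_hat = th_hat, clamped = clamped, capped = capped)
}

#' PD joint torque
#'
#' `tau = p (theta_hat - theta) - d thetadot`: proportional drive toward the
#' target with damping opposing the velocity.  Vectorized over joints.
#'
#' @param theta current angle(s) (rad).
#' @param theta_hat target angle(s) (rad).
#' @param thetadot angular velocity(ies) (rad/s).
#' @param p gain, `d` damping (per joint or scalar).
#' @param d see `p`.
#' @return torque(s) (unit-inertia angular acceleration, rad/s^2).
#' @export
pd_torque <- function(theta, theta_hat, thetadot, p, d) {
  p * (theta_hat - theta) - d * thetadot
}
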