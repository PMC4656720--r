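cfg <- quiet_cfg()

test_that("zero-angle pose puts the wrist at the rest point set by l1 and l2", {
  st <- arm_hand_state(cfg)
  fk <- forward_kinematics(st)
  expect_equal(fk$wrist, c(0, -cfg$arm$l1, -cfg$arm$l2), tolerance = 1e-12)
  expect_equal(sqrt(sum(fk$wrist^2)), sqrt(cfg$arm$l1^2 + cfg$arm$l2^2),
               tolerance = 1e-12)
})

test_that("rotating the elbow by pi/2 moves the wrist along a circle of radius l2", {
  st0 <- arm_hand_state(cfg)
  th <- st0$theta; th[4] <- pi / 2
  st1 <- arm_hand_state(cfg, th)
  d <- forward_kinematics(st1)$wrist - forward_kinematics(st0)$wrist
  # chord of a quarter turn on the elbow circle
  expect_equal(sqrt(sum(d^2)), 2 * cfg$arm$l2 * sin(pi / 4), tolerance = 1e-12)
  # elbow itself does not move
  expect_equal(forward_kinematics(st1)$elbow, forward_kinematics(st0)$elbow)
})

test_that("angles outside joint limits are a domain error", {
  th <- rep(0, 22); th[4] <- 10
  expect_error(arm_hand_state(cfg, th), "limits")
})

test_that("analytic Jacobian matches finite differences over random states", {
  set.seed(42)
  h <- 1e-7
  for (k in 1:50) {
    th <- c(stats::runif(4, -1.5, 1.5), rep(0, 18))
    st <- arm_hand_state(cfg, th)
    J <- jacobian(st)
    w0 <- forward_kinematics(st)$wrist
    fd <- vapply(1:4, function(j) {
      thp <- th; thp[j] <- thp[j] + h
      (forward_kinematics(arm_hand_state(cfg, thp))$wrist - w0) / h
    }, numeric(3))
    expect_lt(max(abs(J - fd)), 1e-5)
  }
})

test_that("Jacobian is linear in the link lengths and zero for a zero-length limb", {
  th <- c(0.3, -0.4, 0.2, 0.9, rep(0, 18))
  st <- arm_hand_state(cfg, th)
  cfg0 <- quiet_cfg(arm = list(l1 = 1e-12, l2 = 1e-12))
  expect_lt(max(abs(jacobian(arm_hand_state(cfg0, th)))), 1e-11)
  cfg2 <- quiet_cfg(arm = list(l1 = 3 * cfg$arm$l1, l2 = 3 * cfg$arm$l2))
  expect_equal(jacobian(arm_hand_state(cfg2, th)), 3 * jacobian(st),
               tolerance = 1e-12)
})

test_that("pseudo-inverse satisfies the Moore-Penrose identities", {
  J <- cbind(diag(3), c(0, 0, 0))
  expect_equal(jacobian_pseudoinverse(J), rbind(diag(3), c(0, 0, 0)),
               tolerance = 1e-12)
  set.seed(7)
  for (k in 1:20) {
    J <- matrix(stats::rnorm(12), 3, 4)
    Jp <- jacobian_pseudoinverse(J)
    expect_lt(max(abs(J %*% Jp %*% J - J)), 1e-8)
    expect_lt(max(abs(Jp %*% J %*% Jp - Jp)), 1e-8)
    # agreement with the SVD pseudo-inverse
    sv <- svd(J)
    Jp_svd <- sv$v %*% diag(1 / sv$d) %*% t(sv$u)
    expect_equal(Jp, Jp_svd, tolerance = 1e-8)
  }
})

test_that("the outstretched arm is reported as singular", {
  th <- rep(0, 22); th[4] <- -pi / 2   # forearm aligned with the upper arm
  st <- arm_hand_state(cfg, th)
  expect_error(jacobian_pseudoinverse(jacobian(st), cfg$arm$cond_cap),
               class = "affgrasp_singularity")
})

test_that("ik_step is the identity for zero displacement and round-trips small ones", {
  th <- c(1.0, -0.3, 0.2, 0.8, rep(0, 18))
  st <- arm_hand_state(cfg, th)
  expect_equal(ik_step(st, c(0, 0, 0))$theta_hat, th[1:4], tolerance = 1e-12)
  set.seed(3)
  for (k in 1:20) {
    d <- stats::runif(3, -1, 1); d <- d / sqrt(sum(d^2)) * 1e-3
    res <- ik_step(st, d)
    th2 <- th; th2[1:4] <- res$theta_hat
    moved <- forward_kinematics(arm_hand_state(cfg, th2))$wrist -
      forward_kinematics(st)$wrist
    expect_lt(sqrt(sum(moved - d)^2), 0.05 * sqrt(sum(d^2)))
  }
})

test_that("out-of-limit IK targets are clamped and flagged", {
  th <- rep(0, 22); th[1:4] <- c(3.05, 0, 0, 0)  # near the shoulder limit
  st <- arm_hand_state(cfg, th)
  res <- ik_step(st, c(0, 0.01, 0))
  expect_true(all(res$theta_hat >= cfg$arm$shoulder_lim[1] - 1e-12))
  expect_true(all(res$theta_hat[1] <= cfg$arm$shoulder_lim[2] + 1e-12))
})

test_that("iterated IK reaches targets in the workspace to under 5 mm", {
  set.seed(11)
  for (k in 1:10) {
    tgt <- sph_to_cart(stats::runif(1, 0.9, 2.2), stats::runif(1, -2.2, -1.1),
                       stats::runif(1, 0.16, 0.26))
    th <- rep(0, 22); th[1] <- 1.6
    st <- arm_hand_state(cfg, th)
    errs <- numeric(0)
    for (it in 1:300) {
      w <- forward_kinematics(st)$wrist
      errs <- c(errs, sqrt(sum((tgt - w)^2)))
      if (errs[length(errs)] < 0.002) break
      res <- ik_step(st, tgt - w)
      st$theta[1:4] <- res$theta_hat
    }
    expect_lt(errs[length(errs)], 0.005)
    late <- errs[seq(ceiling(length(errs) / 2), length(errs))]
    expect_true(all(diff(late) <= 1e-9))
  }
})

test_that("PD torque is zero at the target and proportional off it", {
  expect_equal(pd_torque(0.5, 0.5, 0, 10, 1), 0)
  expect_equal(pd_torque(0, 0.1, 0, 10, 1), 1.0)
  # closed loop on one joint converges without divergence
  th <- 0; thd <- 0; dt <- 0.005
  for (k in 1:1000) {
    tau <- pd_torque(th, 0.7, thd, cfg$arm$pd_p, cfg$arm$pd_d)
    thd <- thd + tau * dt; th <- th + thd * dt
  }
  expect_lt(abs(th - 0.7), 1e-3)
})

test_that("contact detection finds constructed incidences and nothing far away", {
  obj <- test_cube()
  st <- arm_hand_state(cfg)   # hand at rest, far from the cube
  expect_equal(nrow(detect_contacts(st, obj, cfg)), 0)

  # palm center placed exactly on a cube face
  lm <- matrix(obj$position + c(0, -0.02, 0), 3, 1,
               dimnames = list(NULL, "palm"))
  got <- detect_contacts(lm, obj, cfg)
  expect_equal(got$body_part, "palm")

  # thumb and index pads on opposite faces: segment crosses the interior
  pts <- cbind(obj$position + c(0, -0.02, 0), obj$position + c(0, 0.02, 0))
  colnames(pts) <- c("thumb_pad", "finger_pad_1")
  got2 <- detect_contacts(pts, obj, cfg)
  expect_equal(nrow(got2), 2)
  expect_true(segment_through_interior(pts[, 1], pts[, 2], obj))
  # midpoint of the segment lies strictly inside (brute-force oracle)
  expect_lt(object_sdf(obj, (pts[, 1] + pts[, 2]) / 2), 0)
})

test_that("landmarks move away from the surface are not contacts", {
  obj <- test_cube()
  lm <- matrix(obj$position + c(0, -0.021, 0), 3, 1,
               dimnames = list(NULL, "palm"))
  vel_out <- matrix(c(0, -1, 0), 3, 1)
  expect_equal(nrow(detect_contacts(lm, obj, cfg, velocities = vel_out)), 0)
  vel_in <- matrix(c(0, 1, 0), 3, 1)
  expect_equal(nrow(detect_contacts(lm, obj, cfg, velocities = vel_in)), 1)
})

test_that("grasp stability requires an opposition axis held for the full duration", {
  obj <- test_cube()
  opposed <- contact_df(c("thumb_pad", "finger_pad_1"),
                        cbind(obj$position + c(0, -0.02, 0),
                              obj$position + c(0, 0.02, 0)))
  same_face <- contact_df(c("thumb_pad", "finger_pad_1"),
                          cbind(obj$position + c(-0.01, -0.02, 0),
                                obj$position + c(0.01, -0.02, 0)))
  hist_at <- function(df, times) lapply(times, function(t)
    list(time = t, contacts = df))
  tt <- seq(0, 2.0, by = 0.1)
  expect_equal(evaluate_grasp_stability(hist_at(opposed, tt), obj, cfg), "stable")
  expect_equal(evaluate_grasp_stability(hist_at(opposed, seq(0, 1.9, 0.1)),
                                        obj, cfg), "unstable")
  expect_equal(evaluate_grasp_stability(hist_at(same_face, tt), obj, cfg),
               "unstable")
  # interruption resets the clock
  broken <- c(hist_at(opposed, seq(0, 1.5, 0.1)),
              list(list(time = 1.6, contacts = opposed[0, ])),
              hist_at(opposed, seq(1.7, 3.4, 0.1)))
  expect_equal(evaluate_grasp_stability(broken, obj, cfg), "unstable")
})

test_that("stability is invariant under a rigid motion of hand and object", {
  set.seed(21)
  for (k in 1:5) {
    obj <- object_primitive("rectangular_prism", c(0.03, 0.03, 0.12),
                            c(0.05, 0.2, -0.05), stats::runif(3, -1, 1))
    pts <- cbind(obj$position + obj$rot %*% c(0, -0.016, 0),
                 obj$position + obj$rot %*% c(0, 0.016, 0))
    df <- contact_df(c("thumb_pad", "finger_pad_1"), pts)
    hist <- lapply(seq(0, 2, 0.25), function(t) list(time = t, contacts = df))
    v0 <- evaluate_grasp_stability(hist, obj, cfg)
    R <- euler_matrix(stats::runif(3, -1, 1)); tr <- stats::runif(3, -0.1, 0.1)
    obj2 <- object_primitive(obj$shape, obj$size,
                             as.numeric(R %*% obj$position + tr),
                             obj$orientation)
    obj2$rot <- R %*% obj$rot   # rotate the object frame rigidly
    pts2 <- R %*% pts + tr
    df2 <- contact_df(c("thumb_pad", "finger_pad_1"), pts2)
    hist2 <- lapply(seq(0, 2, 0.25), function(t) list(time = t, contacts = df2))
    expect_equal(evaluate_grasp_stability(hist2, obj2, cfg), v0)
  }
})

test_that("collisions displace the object by the configured rule, grasps do not", {
  obj <- test_cube()
  expect_equal(perturb_object_on_collision(obj, obj_con <- data.frame(),
                                           c(1, 0, 0), cfg)$position,
               obj$position)
  # fast palm strike, penetrating 2 mm, no opposition
  pen_pt <- obj$position + c(0, -0.018, 0)
  strike <- contact_df("palm", matrix(pen_pt, 3, 1))
  moved <- perturb_object_on_collision(obj, strike, c(0, 1, 0), cfg)
  pen <- 0.002
  expect_equal(moved$position - obj$position,
               c(0, min(cfg$contact$perturb_gain * pen,
                        cfg$contact$perturb_cap), 0),
               tolerance = 1e-9)
  # opposed pinch is exempt even at speed
  pinch <- contact_df(c("thumb_pad", "finger_pad_1"),
                      cbind(obj$position + c(0, -0.02, 0),
                            obj$position + c(0, 0.02, 0)))
  expect_equal(perturb_object_on_collision(obj, pinch, c(0, 1, 0), cfg)$position,
               obj$position)
  # slow touch is below the knock floor
  slow <- perturb_object_on_collision(obj, strike, c(0, 0.05, 0), cfg)
  expect_equal(slow$position, obj$position)
})

test_that("object primitives validate sizes, normals and spherical pose", {
  expect_error(object_primitive("cube", c(0.1, -0.1, 0.1), c(0, 0.2, 0)),
               "positive")
  obj <- object_primitive("plate", c(0.1, 0.12, 0.006), c(0.05, 0.22, -0.08),
                          c(0.3, -0.2, 0.5))
  expect_equal(colSums(obj$face_normals^2), rep(1, 6), tolerance = 1e-9,
               ignore_attr = TRUE)
  p2 <- sph_to_cart(obj$sph[["theta"]], obj$sph[["phi"]], obj$sph[["rho"]])
  expect_equal(p2, obj$position, tolerance = 1e-9)
})
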