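cfg <- quiet_cfg()

test_that("center-of-mass decoding matches the brute-force weighted mean", {
  # single super-threshold unit: its preferred value
  expect_equal(decode_center_of_mass(c(0, 0.5, 0), list(c(0.1, 0.3, 0.5))),
               0.3)
  # two equal units: the midpoint
  expect_equal(decode_center_of_mass(c(0.4, 0, 0.4), list(c(0.2, 0.3, 0.4))),
               0.3)
  # all units below threshold: no-decode signal
  expect_null(decode_center_of_mass(c(0.005, 0.002), list(c(0, 1)), xi = 0.01))
  # random 2-D field vs direct re-summation with the 0.01 threshold
  set.seed(17)
  pref <- list(seq(0, 1, length.out = 7), seq(-1, 0, length.out = 5))
  f <- matrix(stats::runif(35, 0, 0.2), 7, 5)
  got <- decode_center_of_mass(f, pref, xi = 0.01)
  mask <- f >= 0.01
  expect_equal(got[1], sum(rowSums(f * mask) * pref[[1]]) / sum(f * mask))
  expect_equal(got[2], sum(colSums(f * mask) * pref[[2]]) / sum(f * mask))
})

test_that("virtual-finger selection takes the strongest F5 field, precision on ties", {
  net <- premotor_network(cfg, ag_rng(1))
  for (nm in c("f5e_prec", "f5e_tri", "f5e_pow", "f5e_side")) {
    net$fields[[nm]]$f[] <- 0
  }
  net$fields$f5e_pow$f[7] <- 0.9
  sel <- select_vf(net)
  expect_equal(sel$vf, "power")
  expect_equal(sel$aperture, net$fields$f5e_pow$pref[[1]][7])
  net$fields$f5e_prec$f[3] <- 0.95
  expect_equal(select_vf(net)$vf, "precision")
  net$fields$f5e_tri$f[5] <- 0.95      # exact tie: enum order wins
  expect_equal(select_vf(net)$vf, "precision")
  for (nm in c("f5e_prec", "f5e_tri", "f5e_pow", "f5e_side")) {
    net$fields[[nm]]$f[] <- 0.001
  }
  expect_null(select_vf(net))
})

test_that("reach targets compose the object center with the spherical offset", {
  ctr <- c(theta = 1.5, phi = -1.6, rho = 0.2)
  expect_equal(compose_reach_target(ctr, c(0, -pi / 2, 0), cfg)$target,
               sph_to_cart(1.5, -1.6, 0.2), tolerance = 1e-12)
  off <- compose_reach_target(ctr, c(theta = 0, phi = -pi / 2, rho = 0.1), cfg)
  expect_equal(off$target, sph_to_cart(1.5, -1.6, 0.2) + c(0.1, 0, 0),
               tolerance = 1e-12)
  # opposite offsets are symmetric about the center
  a <- compose_reach_target(ctr, c(0.4, -1.2, 0.05), cfg)$target
  b <- compose_reach_target(ctr, c(0.4 + pi, -pi - (-1.2), 0.05), cfg)$target
  expect_equal((a + b) / 2, sph_to_cart(1.5, -1.6, 0.2), tolerance = 1e-9)
  # out-of-workspace targets are pulled to the boundary and flagged
  far <- compose_reach_target(c(1.5, -1.6, 0.33), c(0, -3.0, 0.1), cfg)
  expect_true(far$clamped)
  expect_lte(sqrt(sum(far$target^2)), 0.95 * (cfg$arm$l1 + cfg$arm$l2) + 1e-9)
})

test_that("the DMP reduces to a damped point attractor and converges to the goal", {
  d <- dmp_state(x0 = c(0, 0, 0), g = c(0.1, -0.05, 0.2), cfg)
  for (k in 1:2000) d <- dmp_step(d, 0.001)
  expect_lt(max(abs(d$x - d$g)), 1e-4)
  # fixed point at the goal
  d2 <- dmp_state(0.3, 0.3, cfg); d2$u <- 1e-9
  d3 <- dmp_step(d2, 0.001)
  expect_equal(d3$x, 0.3, tolerance = 1e-12)
  expect_equal(d3$v, 0, tolerance = 1e-12)
  # phase decays monotonically from 1
  d4 <- dmp_state(0, 1, cfg)
  us <- replicate(100, {d4 <<- dmp_step(d4, 0.005); d4$u})
  expect_true(all(diff(us) < 0) && us[1] < 1)
})

test_that("straight-line basis settings match the closed-form spring trajectory", {
  K <- cfg$motor$dmp_K; D <- cfg$motor$dmp_D
  d <- dmp_state(0, 1, cfg)            # c_i = g - x0: pure point attractor
  x <- 0; v <- 0
  traj_dmp <- traj_ode <- numeric(600)
  for (k in 1:600) {
    d <- dmp_step(d, 0.001)
    a <- K * (1 - x) - D * v           # oracle: direct spring integration
    v <- v + a * 0.001; x <- x + v * 0.001
    traj_dmp[k] <- d$x; traj_ode[k] <- x
  }
  rms <- sqrt(mean((traj_dmp - traj_ode)^2))
  expect_lt(rms, 0.01 * max(abs(traj_ode)))
})

test_that("virtual-finger postures scale linearly with aperture and fail loudly otherwise", {
  p0 <- vf_to_fingers("precision", 0, "preshape")
  p1 <- vf_to_fingers("precision", 1, "preshape")
  ph <- vf_to_fingers("precision", 0.5, "preshape")
  expect_equal(ph, (p0 + p1) / 2, tolerance = 1e-12)
  expect_length(p0, 15)
  # the index opening (MCP flexion) shrinks as aperture drops
  expect_gt(p0[1], p1[1])
  # power enclose flexes all four fingers
  pe <- vf_to_fingers("power", 0.5, "enclose")
  expect_true(all(pe[c(1, 4, 7, 10)] > 1))
  # side grasp keeps fingers enclosed during preshape, thumb extended
  ps <- vf_to_fingers("side", 1, "preshape")
  expect_true(all(ps[c(1, 4, 7, 10)] > 1))
  expect_lt(ps[14], 0.2)
  expect_error(vf_to_fingers("hook", 0.5), "unknown")
  expect_error(vf_to_fingers("power", 1.5), "aperture")
})

test_that("grasp phases interpolate with the timing signal and trigger on proximity or touch", {
  plan <- golden_plan()
  start <- rep(0.2, 15)
  gc <- list(plan = plan, phase = "preshape",
             timing_dmp = timing_dmp(cfg$motor$preshape_duration, cfg),
             start_angles = start, targets = start)
  none <- data.frame()
  # timing ~0: targets stay at the start angles
  gc1 <- grasp_phase_controller(gc, 0.3, none, start, cfg, dt = 1e-6)
  expect_equal(gc1$targets, start, tolerance = 1e-3)
  expect_equal(gc1$phase, "preshape")
  # after the full preshape duration the goal posture is reached
  gcf <- gc
  for (k in 1:400) gcf <- grasp_phase_controller(gcf, 0.3, none, start, cfg, 0.005)
  expect_equal(gcf$targets, vf_to_fingers(plan$vf, plan$aperture, "preshape"),
               tolerance = 1e-2)
  # crossing kappa starts the enclose phase
  gc2 <- grasp_phase_controller(gc, cfg$motor$kappa - 1e-4, none, start, cfg, 0.005)
  expect_equal(gc2$phase, "enclose")
  # palm contact triggers enclose even far from the object
  palm <- contact_df("palm", matrix(c(0, 0.2, 0), 3, 1))
  gc3 <- grasp_phase_controller(gc, 0.3, palm, start, cfg, 0.005)
  expect_equal(gc3$phase, "enclose")
})

test_that("the reach controller freezes on palm contact and survives singularities", {
  st <- arm_hand_state(cfg, c(1.6, rep(0, 21)))
  wr <- forward_kinematics(st)$wrist
  rc <- list(dmp = dmp_state(wr, wr + c(0, 0.1, 0), cfg), halted = FALSE,
             theta_hat = st$theta[1:4], singular = FALSE)
  palm <- contact_df("palm", matrix(c(0, 0.2, 0), 3, 1))
  rc1 <- reach_controller_step(st, rc, palm, 0.005)
  expect_true(rc1$halted)
  expect_equal(rc1$theta_hat, rc$theta_hat)
  rc2 <- reach_controller_step(st, rc, palm[0, ], 0.005)
  expect_false(rc2$halted)
  expect_false(isTRUE(all.equal(rc2$theta_hat, rc$theta_hat)))
})

test_that("grasp plans round-trip through JSON", {
  p <- golden_plan()
  q <- grasp_plan_from_json(grasp_plan_to_json(p))
  expect_s3_class(q, "grasp_plan")
  expect_equal(q$object_center, p$object_center)
  expect_equal(q$wrist, p$wrist, ignore_attr = TRUE)
  expect_identical(q$vf, p$vf)
  # a replayed plan reproduces the same outcome
  res1 <- run_motor_phase(p, test_cube(), quiet_cfg(scale = 10))
  res2 <- run_motor_phase(q, test_cube(), quiet_cfg(scale = 10))
  expect_identical(res1$verdict, res2$verdict)
})

test_that("the golden pinch on a small cube is judged stable end to end", {
  c10 <- quiet_cfg(scale = 10)
  res <- run_motor_phase(golden_plan(), test_cube(), c10)
  expect_true(res$success)
  expect_equal(res$verdict, "stable")
  expect_true(res$palm_contact)
  # deterministic: the motor phase draws no randomness
  res2 <- run_motor_phase(golden_plan(), test_cube(), c10)
  expect_identical(res$final_state$theta, res2$final_state$theta)
  # power grasp from the same approach also succeeds
  expect_true(run_motor_phase(golden_plan("power"), test_cube(), c10)$success)
})

test_that("a plan reaching short of the object ends without contacts or success", {
  plan <- golden_plan()
  plan$object_center["rho"] <- 0.10    # aims 10 cm short
  res <- run_motor_phase(plan, test_cube(), quiet_cfg(scale = 10))
  expect_false(res$success)
  expect_false(res$palm_contact)
})
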