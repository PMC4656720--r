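#' Execute the motor phase of a trial
#'
#' Open-loop control from the decoded grasp plan: the reach DMP drives the
#' wrist to the offset point and then retargets the object center (with the
#' approach speed capped); the wrist PD controllers rotate toward the decoded
#' orientation; the grasp controller runs the preshape and enclose timing
#' DMPs.  Joints are unit-inertia double integrators under PD torque.
#' Contacts are detected geometrically each step; non-grasping collisions can
#' displace the object; the trial succeeds when an opposition axis through
#' the object persists for the hold duration.  Once the system is static the
#' outcome is decided analytically (nothing changes in an open-loop,
#' dynamics-free world), which ends the loop early.
#'
#' @param plan a [decode_grasp_plan()] result.
#' @param object an [object_primitive()].
#' @param cfg an [ag_config()] list.
#' @param start_time simulation time at movement onset (s).
#' @param record_contacts keep the full per-step contact history.
#' @return list(`verdict`, `success`, `palm_contact`, `object`,
#'   `contact_history`, `steps`, `final_state`).
#' @export
run_motor_phase <- function(plan, object, cfg, start_time = 1.05,
                            record_contacts = FALSE) {
  dt <- control_dt(cfg)
  duration <- cfg$training$trial_duration
  hold <- cfg$training$hold_duration
  delta <- cfg$contact$delta
  lim <- joint_limits(cfg)
  theta <- rep(0, 22); theta[1] <- 1.6   # hanging slightly forward
  st <- arm_hand_state(cfg, theta, rep(0, 22))

  tgt <- compose_reach_target(plan$object_center, plan$reach_offset, cfg)
  ctr_est <- sph_to_cart(plan$object_center[1], plan$object_center[2],
                         plan$object_center[3])
  fk <- forward_kinematics(st, check_limits = FALSE)
  rc <- list(dmp = dmp_state(fk$wrist, tgt$target, cfg), halted = FALSE,
             theta_hat = theta[1:4], singular = FALSE, clamped = tgt$clamped)
  # grasp-phase controller with the per-trial posture goals precomputed
  goal_pre <- vf_to_fingers(plan$vf, plan$aperture, "preshape")
  goal_enc <- vf_to_fingers(plan$vf, plan$aperture, "enclose")
  phase <- "preshape"
  tdmp <- timing_dmp(cfg$motor$preshape_duration, cfg)
  phase_start <- theta[8:22]
  wrist_hat <- pmin(pmax(plan$wrist, lim[5:7, 1]), lim[5:7, 2])
  retargeted <- FALSE
  palm_contact <- FALSE
  pair_since <- rep(NA_real_, 15 * 15)   # onset time per landmark pair
  history <- list()
  gains_p <- c(rep(cfg$arm$pd_p, 7), rep(cfg$arm$pd_p_finger, 15))
  gains_d <- c(rep(cfg$arm$pd_d, 7), rep(cfg$arm$pd_d_finger, 15))
  success <- FALSE
  t <- start_time; steps <- 0L
  prev_wrist <- fk$wrist
  near_gate <- 0.25  # skip contact tests while the hand is far away
  limL <- lim[, 1]; limH <- lim[, 2]

  while (t < duration && !success) {
    steps <- steps + 1L
    fk <- forward_kinematics(st, check_limits = FALSE)
    wrist_vel <- (fk$wrist - prev_wrist) / dt
    prev_wrist <- fk$wrist
    d_obj <- sqrt(sum((fk$wrist - object$position)^2))
    hit <- integer(0)
    if (d_obj < near_gate) {
      sd <- object_sdf(object, fk$landmarks)
      hit <- which(sd <= delta & sd >= -(delta + 0.02))
    }
    pairs_now <- integer(0)
    if (length(hit) > 0) {
      if (1L %in% hit) palm_contact <- TRUE
      # opposing pairs whose axis passes through the object
      if (length(hit) >= 2) {
        for (a in seq_len(length(hit) - 1)) for (b in seq(a + 1, length(hit))) {
          i <- hit[a]; j <- hit[b]
          ga <- landmark_groups[i]; gb <- landmark_groups[j]
          opp <- (ga == "thumb" && gb == "finger") ||
            (ga == "finger" && gb == "thumb") ||
            (ga == "palm") != (gb == "palm")
          if (!opp) next
          if (segment_through_interior(fk$landmarks[, i], fk$landmarks[, j],
                                       object, cfg$contact$interior_depth)) {
            pairs_now <- c(pairs_now, (i - 1L) * 15L + j)
          }
        }
      }
      object <- perturb_impl(object, fk$landmarks[, hit, drop = FALSE],
                             wrist_vel, length(pairs_now) > 0, cfg)
    }
    if (length(pairs_now) > 0) {
      fresh <- is.na(pair_since[pairs_now])
      pair_since[pairs_now[fresh]] <- t
      if (any(t - pair_since[pairs_now] >= hold - 1e-9)) success <- TRUE
    }
    off <- setdiff(which(!is.na(pair_since)), pairs_now)
    if (length(off)) pair_since[off] <- NA_real_
    if (record_contacts) {
      history[[length(history) + 1]] <- list(
        time = t,
        contacts = data.frame(body_part = landmark_names[hit],
                              x = fk$landmarks[1, hit],
                              y = fk$landmarks[2, hit],
                              z = fk$landmarks[3, hit],
                              time = rep(t, length(hit)),
                              row.names = NULL, stringsAsFactors = FALSE))
    }
    if (success) break

    # reach controller (halts permanently on palm or inner-thumb contact)
    halt_now <- (1L %in% hit) || (15L %in% hit)
    rc <- reach_step_impl(st, rc, halt_now, dt, fk$wrist)
    if (!retargeted && !rc$halted &&
        sqrt(sum((fk$wrist - rc$dmp$g)^2)) < 0.015) {
      rc$dmp <- dmp_retarget(rc$dmp, ctr_est)
      retargeted <- TRUE
    }
    if (retargeted) {  # cap the final-approach speed
      vn <- sqrt(sum(rc$dmp$v^2))
      if (vn > cfg$motor$approach_speed_cap) {
        rc$dmp$v <- rc$dmp$v * (cfg$motor$approach_speed_cap / vn)
      }
    }
    # grasp phases: preshape from reach onset, enclose at kappa or palm touch
    if (phase == "preshape" && (d_obj < cfg$motor$kappa || 1L %in% hit)) {
      phase <- "enclose"
      phase_start <- st$theta[8:22]
      tdmp <- timing_dmp(cfg$motor$enclose_duration, cfg)
    }
    tdmp <- dmp_step(tdmp, dt)
    w <- min(1, max(0, tdmp$x))
    goal <- if (phase == "enclose") goal_enc else goal_pre
    fingers_hat <- phase_start + w * (goal - phase_start)

    theta_hat <- c(rc$theta_hat, wrist_hat,
                   pmin(pmax(fingers_hat, limL[8:22]), limH[8:22]))
    # unit-inertia PD integration
    tau <- gains_p * (theta_hat - st$theta) - gains_d * st$thetadot
    st$thetadot <- st$thetadot + tau * dt
    st$theta <- st$theta + st$thetadot * dt
    cl <- st$theta < limL; ch <- st$theta > limH
    if (any(cl)) { st$theta[cl] <- limL[cl]; st$thetadot[cl] <- 0 }
    if (any(ch)) { st$theta[ch] <- limH[ch]; st$thetadot[ch] <- 0 }
    t <- t + dt

    # static-system shortcuts: open loop, no dynamics -> outcome decided
    static_now <- max(abs(st$thetadot)) < 0.05
    if (phase == "enclose" && tdmp$x > 0.995 && static_now) {
      on <- which(!is.na(pair_since))
      success <- length(on) > 0 && any(duration - pair_since[on] >= hold)
      break
    }
    if (phase == "preshape" && tdmp$x > 0.995 && static_now &&
        length(hit) == 0 && d_obj > cfg$motor$kappa &&
        (rc$halted || sqrt(sum((fk$wrist - rc$dmp$g)^2)) < 0.005)) {
      break  # settled short of the object with nothing in reach
    }
  }
  list(verdict = if (success) "stable" else "unstable", success = success,
       palm_contact = palm_contact, object = object,
       contact_history = history, steps = steps, final_state = st,
       plan = plan)
}

#' Run one training trial
#'
#' The trial protocol: the object appears at 0.5 s and is encoded by the
#' parietal populations; preparation fields settle; at 1 s the go signal
#' releases the execution fields, the plan is decoded and the movement runs
#' until the trial ends at 5 s (or the outcome is decided).  The
#' reinforcement signal occupies the last five control steps: in the grasp
#' stage `DA_success` on a stable grasp and `DA_fail` otherwise; in the
#' wrist stage `DA_success / 4` if palm contact occurred at all (else 0); in
#' the AIP stage no movement is attempted and `rs = 0` throughout.
#' Learning scope per stage: AIP stage updates only the affordance map;
#' wrist stage only the F7 -> wrist projection; grasp stage the map plus
#' every learned premotor projection.
#'
#' @param model a [grasp_model()].
#' @param object an [object_primitive()].
#' @param stage `"aip"`, `"wrist"` or `"grasp"`.
#' @param trial trial index for the record.
#' @return list(`model`, `record` one-row data.frame, `aip` activity vector).
#' @export
run_trial <- function(model, object, stage = c("aip", "wrist", "grasp"),
                      trial = NA_integer_) {
  stage <- match.arg(stage)
  cfg <- model$cfg
  rng <- model$rng
  enc <- with_stream(rng, "noise", encode_scene(object, cfg))
  aip <- with_stream(rng, "noise", aip_activity(model$som, enc$aip_input))
  rs <- 0; success <- FALSE; palm <- FALSE; verdict <- NA_character_
  plan <- NULL
  if (stage != "aip") {
    model$net <- with_stream(rng, "noise",
      settle_premotor(model$net, aip, enc, cfg))
    plan <- decode_grasp_plan(model$net, cfg)
    if (!is.null(plan)) {
      res <- run_motor_phase(plan, object, cfg,
                             start_time = cfg$training$go_time +
                               model$net$params$exec_settle)
      success <- res$success; palm <- res$palm_contact
      verdict <- res$verdict
    }
    rs <- if (stage == "grasp") {
      if (success) cfg$reward$da_success else cfg$reward$da_fail
    } else {
      if (palm) cfg$reward$da_success / 4 else 0
    }
  }
  # learning, per stage scope
  if (stage == "aip") {
    model$som <- som_update(model$som, enc$aip_input, 0)
  } else if (stage == "wrist") {
    model$net <- premotor_learn(model$net, aip, rs, cfg, scope = "wrist")
  } else {
    model$som <- som_update(model$som, enc$aip_input, max(rs, 0))
    model$net <- premotor_learn(model$net, aip, rs, cfg, scope = "all")
  }
  rec <- data.frame(
    trial = trial, stage = stage,
    novel = isTRUE(attr(object, "novel")),
    shape = object$shape,
    s_x = object$size[1], s_y = object$size[2], s_z = object$size[3],
    theta_s = object$sph[["theta"]], phi_s = object$sph[["phi"]],
    rho_s = object$sph[["rho"]],
    o_x = object$orientation[1], o_y = object$orientation[2],
    o_z = object$orientation[3],
    attempted = !is.null(plan),
    vf = if (is.null(plan)) NA_character_ else plan$vf,
    aperture = if (is.null(plan)) NA_real_ else plan$aperture,
    palm_contact = palm, success = success, rs = rs,
    stringsAsFactors = FALSE)
  list(model = model, record = rec, aip = as.numeric(aip))
}
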