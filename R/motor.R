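#' Compose the Cartesian reach target
#'
#' Adds the object-centered reach offset (spherical, expressed in the
#' world-aligned frame at the object center) to the shoulder-centered object
#' center.  Targets beyond the reachable workspace are pulled back to the
#' boundary and flagged.
#'
#' @param object_center c(theta, phi, rho) shoulder-centered spherical.
#' @param reach_offset c(theta, phi, rho) object-centered spherical.
#' @param cfg an [ag_config()] list.
#' @return list(`target` 3-vector (m), `clamped` logical).
#' @export
compose_reach_target <- function(object_center, reach_offset, cfg) {
  ctr <- sph_to_cart(object_center[[1]], object_center[[2]], object_center[[3]])
  off <- sph_to_cart(reach_offset[[1]], reach_offset[[2]], reach_offset[[3]])
  tgt <- unname(ctr + off)
  rmax <- 0.95 * (cfg$arm$l1 + cfg$arm$l2)
  clamped <- FALSE
  nrm <- sqrt(sum(tgt^2))
  if (nrm > rmax) { tgt <- tgt * (rmax / nrm); clamped <- TRUE }
  list(target = tgt, clamped = clamped)
}

#' Dynamic movement primitive state
#'
#' A damped point attractor with a phase-gated forcing term:
#' `vdot = u K (sum_i psi_i(u) (c_i + x0) / sum_i psi_i(u) - x)
#'         + (1 - u) K (g - x) - D v`,
#' with phase `u` decaying from 1 as `udot = -alpha_u u`.  The basis
#' functions `psi_i` are Gaussians equally spaced in phase, overlapping at
#' half height.  The default equilibrium points `c_i = g - x0` reduce the
#' dynamics to a straight-line point attractor (no shaped trajectory).
#' Works componentwise for vector-valued `x`.
#'
#' @param x0 start value(s).
#' @param g goal value(s).
#' @param cfg an [ag_config()] list (`motor` block).
#' @param c_i optional basis equilibrium points (n_basis x length(x0)).
#' @return an object of class `"dmp_state"`.
#' @export
dmp_state <- function(x0, g, cfg, c_i = NULL) {
  m <- cfg$motor
  nb <- m$dmp_n_basis
  centers <- seq(1, 0, length.out = nb)        # basis centers in phase
  width <- (centers[1] - centers[2])           # spacing
  if (is.null(c_i)) c_i <- matrix(rep(g - x0, each = nb), nrow = nb)
  structure(list(x = x0, v = x0 * 0, u = 1, x0 = x0, g = g,
                 K = m$dmp_K, D = m$dmp_D, alpha_u = m$dmp_alpha_u,
                 centers = centers,
                 h = 1 / (2 * (width / sqrt(2 * log(2)))^2),  # half-height overlap
                 c_i = c_i),
            class = "dmp_state")
}

#' One explicit-Euler DMP step
#' @param dmp a [dmp_state()].
#' @param dt time step (s).
#' @return the updated `dmp_state`.
#' @export
dmp_step <- function(dmp, dt) {
  psi <- exp(-dmp$h * (dmp$u - dmp$centers)^2)
  forcing <- as.numeric(crossprod(psi, dmp$c_i)) / sum(psi) + dmp$x0
  vdot <- dmp$u * dmp$K * (forcing - dmp$x) +
    (1 - dmp$u) * dmp$K * (dmp$g - dmp$x) - dmp$D * dmp$v
  dmp$v <- dmp$v + vdot * dt
  dmp$x <- dmp$x + dmp$v * dt
  dmp$u <- max(dmp$u - dmp$alpha_u * dmp$u * dt, 1e-9)
  dmp
}

#' Set a new goal for a running DMP (retargeting)
#' @param dmp a [dmp_state()].
#' @param g new goal value(s).
#' @return the `dmp_state` with straight-line basis toward the new goal.
#' @export
dmp_retarget <- function(dmp, g) {
  dmp$g <- g
  dmp$c_i <- matrix(rep(g - dmp$x0, each = length(dmp$centers)),
                    nrow = length(dmp$centers))
  dmp
}

#' A normalized 0-to-1 timing DMP
#'
#' The grasp controller reuses the DMP machinery as a timing signal: start 0,
#' goal 1, gains chosen so the critically damped rise completes (99%) in
#' `duration` seconds.
#'
#' @param duration rise time (s).
#' @param cfg an [ag_config()] list.
#' @return a [dmp_state()].
#' @export
timing_dmp <- function(duration, cfg) {
  omega <- 6.6 / duration
  d <- dmp_state(0, 1, cfg)
  d$K <- omega^2; d$D <- 2 * omega
  d$alpha_u <- log(100) / duration
  d
}

vf_levels <- c("precision", "tripod", "power", "side")

#' Serialize or restore a grasp plan as JSON
#'
#' Round-trippable plan serialization for replay and golden-trial tests.
#' @param plan a `grasp_plan` (see [decode_grasp_plan()]).
#' @return JSON string.
#' @export
grasp_plan_to_json <- function(plan) {
  stopifnot(inherits(plan, "grasp_plan"))
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("plan serialization needs the 'jsonlite' package", call. = FALSE)
  }
  x <- unclass(plan)
  for (nm in c("object_center", "reach_offset", "wrist")) {
    x[[nm]] <- as.list(stats::setNames(as.numeric(x[[nm]]),
                                       names(x[[nm]])))  # keep names in JSON
  }
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
}

#' @rdname grasp_plan_to_json
#' @param json JSON string written by [grasp_plan_to_json()].
#' @export
grasp_plan_from_json <- function(json) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("plan serialization needs the 'jsonlite' package", call. = FALSE)
  }
  x <- jsonlite::fromJSON(json)
  for (nm in c("object_center", "reach_offset", "wrist")) {
    x[[nm]] <- unlist(x[[nm]])
  }
  structure(x, class = "grasp_plan")
}

#' The virtual-finger posture table
#'
#' Per-combination finger postures (15 DOFs: four fingers x MCP/PIP/DIP,
#' thumb abduction/flexion/MCP): `open` is the fully open preshape
#' (aperture 1), `closed_pre` the minimal-opening preshape (aperture 0),
#' `enclose` the closing posture that brings the involved digits onto the
#' opposition axis.
#'
#' @return named list over combinations, each with `open`, `closed_pre`,
#'   `enclose` numeric 15-vectors (rad).
#' @export
vf_posture_table <- function() {
  fin <- function(m, p, d) c(m, p, d)
  curl <- fin(1.5, 1.2, 0.9)     # digit folded out of the way
  ext  <- fin(0.05, 0.05, 0.05)  # digit straight
  list(
    precision = list(
      open       = c(ext, curl, curl, curl,  0.95, 0.15, 0.10),
      closed_pre = c(fin(0.7, 0.5, 0.3), curl, curl, curl,  0.95, 0.55, 0.35),
      enclose    = c(fin(1.0, 0.8, 0.6), curl, curl, curl,  0.95, 0.85, 0.55)),
    tripod = list(
      open       = c(ext, ext, curl, curl,  0.95, 0.15, 0.10),
      closed_pre = c(fin(0.7, 0.5, 0.3), fin(0.7, 0.5, 0.3), curl, curl,
                     0.95, 0.55, 0.35),
      enclose    = c(fin(1.0, 0.8, 0.6), fin(1.0, 0.8, 0.6), curl, curl,
                     0.95, 0.85, 0.55)),
    power = list(
      open       = c(ext, ext, ext, ext,  0.35, 0.10, 0.10),
      closed_pre = c(fin(0.5, 0.4, 0.3), fin(0.5, 0.4, 0.3),
                     fin(0.5, 0.4, 0.3), fin(0.5, 0.4, 0.3),
                     0.35, 0.35, 0.25),
      enclose    = c(fin(1.35, 1.1, 0.85), fin(1.35, 1.1, 0.85),
                     fin(1.35, 1.1, 0.85), fin(1.35, 1.1, 0.85),
                     0.55, 0.75, 0.55)),
    side = list(
      open       = c(fin(1.2, 1.0, 0.8), fin(1.2, 1.0, 0.8),
                     fin(1.2, 1.0, 0.8), fin(1.2, 1.0, 0.8),
                     0.15, 0.05, 0.05),
      closed_pre = c(fin(1.2, 1.0, 0.8), fin(1.2, 1.0, 0.8),
                     fin(1.2, 1.0, 0.8), fin(1.2, 1.0, 0.8),
                     0.15, 0.35, 0.25),
      enclose    = c(fin(1.2, 1.0, 0.8), fin(1.2, 1.0, 0.8),
                     fin(1.2, 1.0, 0.8), fin(1.2, 1.0, 0.8),
                     0.35, 0.75, 0.55)))
}

#' Map a virtual-finger combination to per-joint finger targets
#'
#' Returns the 15 finger-DOF target angles for the given grasp phase.  In
#' the preshape phase the maximum-aperture parameter linearly interpolates
#' the opening of the involved digits between the minimal and maximal
#' preshape configurations; uninvolved digits hold the combination's default
#' (e.g. side grasp: fingers stay enclosed, thumb extended).  The enclose
#' posture is aperture-independent.
#'
#' @param vf one of `"precision"`, `"tripod"`, `"power"`, `"side"`.
#' @param aperture maximum aperture in `[0, 1]`.
#' @param phase `"preshape"` or `"enclose"`.
#' @return numeric 15-vector of target angles (rad).
#' @export
vf_to_fingers <- function(vf, aperture, phase = c("preshape", "enclose")) {
  phase <- match.arg(phase)
  if (!vf %in% vf_levels) stop("unknown virtual-finger combination: ", vf,
                               call. = FALSE)
  if (aperture < 0 || aperture > 1) stop("aperture must lie in [0, 1]",
                                         call. = FALSE)
  tab <- vf_posture_table()[[vf]]
  if (phase == "enclose") return(tab$enclose)
  tab$closed_pre + aperture * (tab$open - tab$closed_pre)
}

#' One reach-controller step
#'
#' Advances the wrist DMP toward the current goal, converts the resulting
#' waypoint displacement into shoulder/elbow targets through [ik_step()],
#' and freezes the reach on palm or inner-thumb contact.  An IK singularity
#' holds the previous targets and flags the step.
#'
#' @param state an [arm_hand_state()].
#' @param rc reach-controller state: list(`dmp`, `halted`, `theta_hat`).
#' @param contacts current contact data.frame.
#' @param dt control step (s).
#' @return the updated `rc` (with `theta_hat` the 4 arm joint targets).
#' @export
reach_controller_step <- function(state, rc, contacts, dt) {
  halt <- nrow(contacts) > 0 &&
    any(contacts$body_part %in% c("palm", "thumb_side"))
  reach_step_impl(state, rc, halt, dt,
                  forward_kinematics(state, check_limits = FALSE)$wrist)
}

reach_step_impl <- function(state, rc, halt_now, dt, wrist_now) {
  if (!rc$halted && halt_now) rc$halted <- TRUE
  if (rc$halted) return(rc)
  rc$dmp <- dmp_step(rc$dmp, dt)
  res <- tryCatch(ik_step(state, rc$dmp$x - wrist_now),
                  affgrasp_singularity = function(e) NULL)
  if (is.null(res)) {
    rc$singular <- TRUE
  } else {
    rc$theta_hat <- res$theta_hat
    rc$clamped <- res$clamped
  }
  rc
}

#' One grasp-phase-controller step
#'
#' Runs the preshape and enclose timing DMPs: the preshape starts with the
#' reach; the enclose starts when the wrist comes within `kappa` of the
#' object or on palm contact, whichever happens first.  The timing signal in
#' `[0, 1]` interpolates from the phase's start posture toward its target
#' posture.
#'
#' @param gc grasp-controller state: list(`plan`, `phase`, `timing_dmp`,
#'   `start_angles`).
#' @param wrist_object_distance current wrist-to-object-center distance (m).
#' @param contacts current contact data.frame.
#' @param finger_angles current 15 finger joint angles.
#' @param cfg an [ag_config()] list.
#' @param dt control step (s).
#' @return updated `gc` with `targets`, the 15 finger joint targets.
#' @export
grasp_phase_controller <- function(gc, wrist_object_distance, contacts,
                                   finger_angles, cfg, dt) {
  palm <- nrow(contacts) > 0 && any(contacts$body_part == "palm")
  if (gc$phase == "preshape" &&
      (wrist_object_distance < cfg$motor$kappa || palm)) {
    gc$phase <- "enclose"
    gc$start_angles <- finger_angles
    gc$timing_dmp <- timing_dmp(cfg$motor$enclose_duration, cfg)
  }
  gc$timing_dmp <- dmp_step(gc$timing_dmp, dt)
  w <- min(1, max(0, gc$timing_dmp$x))
  goal <- vf_to_fingers(gc$plan$vf, gc$plan$aperture,
                        if (gc$phase == "enclose") "enclose" else "preshape")
  gc$targets <- gc$start_angles + w * (goal - gc$start_angles)
  gc
}
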