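#' Default model configuration
#'
#' Builds the full configuration list for the simulator: arm/hand geometry and
#' joint limits, contact tolerances, parietal population-code layouts, the
#' affordance-map (SOM) parameters, dynamic-neural-field parameters, premotor
#' grid sizes and learning rates, motor-controller constants, reward
#' magnitudes, and the trial protocol.  Every free parameter of the model is
#' exposed here; [load_config()] reads overrides from a YAML file.
#'
#' All angles are in radians, lengths in meters, times in seconds.  The
#' coordinate frame is right-handed and shoulder-centered: at rest (all joint
#' angles zero) the upper arm points along \eqn{-y} and the forearm along
#' \eqn{-z}; objects are presented in the \eqn{y > 0} hemispace.
#'
#' @param ... named overrides.  Nested values are addressed by list, e.g.
#'   `ag_config(som = list(lambda = 500))`.  Unknown keys are an error.
#' @return a named list of class `"ag_config"`.
#' @export
ag_config <- function(...) {
  cfg <- list(
    seed  = 1L,
    # global run-scale: trial counts are divided by `scale`; the control time
    # step is multiplied by it, capped at tau/2 for DNF stability.
    scale = 1,
    arm = list(
      l1 = 0.17, l2 = 0.17,
      palm_length = 0.050,   # wrist -> finger MCP row
      palm_width  = 0.040,
      finger_segments = c(0.028, 0.020, 0.014),
      thumb_segments  = c(0.026, 0.018),
      finger_spread   = c(0.018, 0.006, -0.006, -0.018),  # MCP x-offsets
      thumb_base      = c(0.028, 0.0, -0.015),            # in hand frame
      # joint limits: shoulder xyz, elbow, wrist xyz, 15 finger DOFs
      shoulder_lim = c(-3.1, 3.1),
      elbow_lim    = c(-2.6, 2.6),
      wrist_lim    = c(-1.3, 1.3),
      finger_lim   = c(-0.3, 1.8),
      thumb_ab_lim = c(-1.2, 1.2),
      pd_p = 400, pd_d = 40,          # arm/wrist joints (unit inertia)
      pd_p_finger = 600, pd_d_finger = 49,
      ik_step_cap = 0.01,             # max wrist displacement per IK step (m)
      cond_cap = 1e8                  # J J^T condition-number singularity cap
    ),
    contact = list(
      delta = 0.005,        # landmark-to-surface contact tolerance (m)
      interior_depth = 1e-3,# segment must penetrate this deep to "pass through"
      perturb_gain = 0.3,   # object displacement per meter of penetration
      perturb_cap  = 0.005, # max displacement per control step (m)
      speed_floor  = 0.30   # hand speed (m/s) below which no knock occurs
    ),
    view_dir = c(0, 1, 0),  # gaze direction; a face is visible iff n . v < 0
    parietal = list(
      dist = list(n = 15L, range = c(0, 1), sigma = 0.10),
      dir  = list(n = c(15L, 15L), theta_range = c(0, pi),
                  phi_range = c(-pi, 0), sigma = 0.10),
      cips = list(n = c(11L, 11L, 11L), sigma = 0.08,
                  comp_range = c(-1, 1),   # axis/normal components
                  size_range = c(0, 1),    # normalized sizes
                  size_max = 0.25),        # meters mapped to normalized 1.0
      noise_sd = 0.01
    ),
    som = list(
      n = 40L, r0 = 20, lambda = 350, alpha0 = 1.5,
      init_max = 0.01, noise_sd = 0.01
    ),
    dnf = list(
      tau = 0.010, h = -1, beta = 6, u0 = 0.4,
      w_excite = 2, w_inhibit = 1.5, sigma = 2, noise_sd = 0.05
    ),
    premotor = list(
      n_dir = 15L, n_rad = 15L, n_f5 = 11L, n_wr = 9L,
      offset_rho_max = 0.10,          # F7 radius field range [0, max]
      f5_cross = 0.25,                # W_F5s->F5s inter-field inhibition
      gp = 10,                        # tonic inhibition before the go signal
      w_init_max = 0.022,
      alpha_f7 = 2e-3, alpha_f5 = 2e-3, alpha_wr = 2e-3,
      w_cap = 0.3,                    # saturation bound on learned weights
      prep_settle = 0.40,             # s of preparation-field settling
      exec_settle = 0.05              # s between go signal and decode
    ),
    motor = list(
      xi = 0.01,                      # center-of-mass decode threshold
      kappa = 0.06,                   # wrist-object distance enclose trigger
      dmp_K = 100, dmp_D = 20, dmp_alpha_u = log(100) / 1.5,
      dmp_n_basis = 10L,
      movement_duration = 1.5,
      preshape_duration = 0.8,
      enclose_duration  = 0.5,
      approach_speed_cap = 0.15       # m/s during final approach
    ),
    reward = list(da_success = 1, da_fail = -0.2),
    training = list(
      trial_duration = 5, dt = 0.001,
      object_onset = 0.5, go_time = 1.0,
      reward_steps = 5L, hold_duration = 2,
      object_refresh = 6L,
      n_aip = 1000L, n_wrist = 2000L, n_grasp = 10000L,
      wrist_stop_rate = 0.6, wrist_stop_window = 200L,
      novel_fraction = 0.5            # probe onset, as fraction of grasp stage
    ),
    objects = list(
      shapes = c("cube", "rectangular_prism", "cylinder", "sphere", "plate"),
      azimuth_range   = c(0.9, 2.2),
      elevation_range = c(-2.2, -1.1),
      rho_range       = c(0.16, 0.26),
      orientation_max = pi / 3,       # |Euler angle| cap when sampling
      # per-shape size ranges (m): each shape occupies a characteristic
      # region of size space (small blocks, elongated thin prisms, thicker
      # cylinders, mid-sized balls, broad thin plates)
      size = list(
        cube              = list(side = c(0.020, 0.055)),
        rectangular_prism = list(cross = c(0.015, 0.035), length = c(0.10, 0.16)),
        cylinder          = list(diam  = c(0.055, 0.085), length = c(0.09, 0.15)),
        sphere            = list(diam  = c(0.070, 0.100)),
        plate             = list(side  = c(0.09, 0.15), thick = c(0.004, 0.012))
      ),
      novel = list(                   # probe ranges, disjoint from the above
        azimuth_range   = c(1.0, 2.1),
        elevation_range = c(-2.0, -1.3),
        rho_range       = c(0.26, 0.285),
        size_scale      = 0.90        # sizes scaled below the training intervals
      )
    )
  )
  cfg <- merge_config(cfg, list(...), path = "")
  validate_config(cfg)
  class(cfg) <- "ag_config"
  cfg
}

# recursive override with unknown-key rejection
merge_config <- function(base, override, path = "") {
  if (length(override) == 0) return(base)
  nm <- names(override)
  if (is.null(nm) || any(nm == "")) {
    stop("config overrides must be named (at '", path, "')", call. = FALSE)
  }
  for (k in nm) {
    here <- if (nzchar(path)) paste0(path, "$", k) else k
    if (!k %in% names(base)) {
      stop("unknown configuration key: '", here, "'", call. = FALSE)
    }
    if (is.list(base[[k]]) && !is.list(override[[k]])) {
      stop("configuration key '", here, "' must be a list", call. = FALSE)
    }
    if (is.list(base[[k]])) {
      base[[k]] <- merge_config(base[[k]], override[[k]], here)
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid config: ", msg, call. = FALSE)
  chk(cfg$scale >= 1, "scale must be >= 1")
  chk(cfg$arm$l1 > 0 && cfg$arm$l2 > 0, "arm$l1 and arm$l2 must be positive")
  chk(cfg$contact$delta > 0, "contact$delta must be positive")
  chk(cfg$parietal$dist$sigma > 0 && cfg$parietal$dir$sigma > 0 &&
        cfg$parietal$cips$sigma > 0, "population sigmas must be positive")
  chk(cfg$parietal$noise_sd >= 0, "parietal$noise_sd must be >= 0")
  chk(cfg$som$n >= 2 && cfg$som$r0 > 0 && cfg$som$lambda > 0 &&
        cfg$som$alpha0 > 0, "som parameters out of range")
  chk(cfg$dnf$tau > 0 && cfg$dnf$w_excite > 0 && cfg$dnf$w_inhibit >= 0,
      "dnf parameters out of range")
  chk(cfg$motor$xi > 0, "motor$xi must be positive")
  chk(cfg$motor$kappa > 0, "motor$kappa must be positive")
  chk(cfg$reward$da_success > 0 && cfg$reward$da_fail < 0,
      "reward must satisfy da_success > 0 > da_fail")
  chk(cfg$training$dt > 0 && cfg$training$trial_duration > 0,
      "trial timing out of range")
  chk(cfg$training$reward_steps >= 1, "reward_steps must be >= 1")
  chk(length(cfg$objects$shapes) >= 1, "objects$shapes must be non-empty")
  invisible(cfg)
}

#' Effective control time step after applying the run scale
#'
#' The control step is the base `training$dt` multiplied by `scale`, capped at
#' `tau / 2` so explicit-Euler field integration stays stable.
#' @param cfg an [ag_config()] list.
#' @return time step in seconds.
#' @export
control_dt <- function(cfg) {
  min(cfg$training$dt * cfg$scale, cfg$dnf$tau / 2)
}

#' Read a configuration from a YAML file
#'
#' Missing keys take their defaults from [ag_config()]; unknown keys are
#' rejected with the offending key path.  An empty file yields the full
#' default configuration.
#'
#' @param path YAML file path.
#' @return an `ag_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  do.call(ag_config, raw)
}

#' Write a configuration to a YAML file
#' @param cfg an `ag_config` list.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15L)
  invisible(path)
}

#' @export
print.ag_config <- function(x, ...) {
  cat("<affgrasp configuration>\n")
  cat("  seed:", x$seed, " scale:", x$scale,
      " control dt:", control_dt(x), "s\n")
  cat("  arm: l1 =", x$arm$l1, "m, l2 =", x$arm$l2, "m, 22 DOF\n")
  cat("  SOM:", x$som$n, "x", x$som$n, " r0 =", x$som$r0,
      " lambda =", x$som$lambda, " alpha0 =", x$som$alpha0, "\n")
  cat("  stages:", x$training$n_aip, "AIP /", x$training$n_wrist,
      "wrist /", x$training$n_grasp, "grasp trials (before scaling)\n")
  invisible(x)
}
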