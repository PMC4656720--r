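#' Construct the premotor reach-and-grasp planning network
#'
#' Preparation- and execution-related dynamic neural fields for each planned
#' parameter: F2vr/F2d encode the shoulder-centered object direction (2-D)
#' and distance (1-D); F7 the object-centered reach offset direction (2-D)
#' and radius (1-D); F5 one 1-D field per virtual-finger combination
#' (precision, tripod, power, side) over maximum aperture; F2/F5 the wrist
#' rotation (3-D over the wrist joint ranges).  Parietal input reaches F2
#' through fixed identity weights scaled by 3; preparation fields relay to
#' their execution counterparts through fixed identity weights scaled by 2;
#' every other afferent is a learned matrix initialized to small random
#' values and trained by the reinforcement rule.
#'
#' @param cfg an [ag_config()] list.
#' @param rng an [ag_rng()] (stream `"init"`), or `NULL`.
#' @return an object of class `"premotor_network"`.
#' @export
premotor_network <- function(cfg, rng = NULL) {
  pm <- cfg$premotor
  dnf <- cfg$dnf
  n_aip <- cfg$som$n^2
  dir_rng <- list(cfg$parietal$dir$theta_range, cfg$parietal$dir$phi_range)
  off_rng <- list(c(-pi, pi), c(-pi, 0))
  wr_rng <- rep(list(cfg$arm$wrist_lim), 3)
  mk <- function(dims, n, ranges) dnf_field(dims, n, ranges, dnf)
  fields <- list(
    f2vr_dir = mk(2, pm$n_dir, dir_rng),
    f2vr_rad = mk(1, pm$n_rad, list(cfg$parietal$dist$range)),
    f2d_dir  = mk(2, pm$n_dir, dir_rng),
    f2d_rad  = mk(1, pm$n_rad, list(cfg$parietal$dist$range)),
    f7s_dir  = mk(2, pm$n_dir, off_rng),
    f7s_rad  = mk(1, pm$n_rad, list(c(0, pm$offset_rho_max))),
    f7e_dir  = mk(2, pm$n_dir, off_rng),
    f7e_rad  = mk(1, pm$n_rad, list(c(0, pm$offset_rho_max))),
    f5s_prec = mk(1, pm$n_f5, list(c(0, 1))),
    f5s_tri  = mk(1, pm$n_f5, list(c(0, 1))),
    f5s_pow  = mk(1, pm$n_f5, list(c(0, 1))),
    f5s_side = mk(1, pm$n_f5, list(c(0, 1))),
    f5e_prec = mk(1, pm$n_f5, list(c(0, 1))),
    f5e_tri  = mk(1, pm$n_f5, list(c(0, 1))),
    f5e_pow  = mk(1, pm$n_f5, list(c(0, 1))),
    f5e_side = mk(1, pm$n_f5, list(c(0, 1))),
    wrs      = mk(3, pm$n_wr, wr_rng),
    wre      = mk(3, pm$n_wr, wr_rng))
  n_dir2 <- pm$n_dir^2; n_wr3 <- pm$n_wr^3
  init_w <- function(nr, nc) {
    draw <- function() matrix(stats::runif(nr * nc, 0, pm$w_init_max), nr, nc)
    if (is.null(rng)) draw() else with_stream(rng, "init", draw())
  }
  W <- list(
    aip_f7dir = init_w(n_aip, n_dir2),
    aip_f7rad = init_w(n_aip, pm$n_rad),
    f2_f7     = init_w(n_dir2, n_dir2),
    aip_f5_prec = init_w(n_aip, pm$n_f5),
    aip_f5_tri  = init_w(n_aip, pm$n_f5),
    aip_f5_pow  = init_w(n_aip, pm$n_f5),
    aip_f5_side = init_w(n_aip, pm$n_f5),
    aip_wr = init_w(n_aip, n_wr3),
    f7_wr  = init_w(n_dir2, n_wr3),
    f5_wr_prec = init_w(pm$n_f5, n_wr3),
    f5_wr_tri  = init_w(pm$n_f5, n_wr3),
    f5_wr_pow  = init_w(pm$n_f5, n_wr3),
    f5_wr_side = init_w(pm$n_f5, n_wr3))
  structure(list(fields = fields, W = W,
                 fixed = list(parietal_f2 = 3, relay = 2,
                              f5_cross = pm$f5_cross),
                 gp = pm$gp, go = FALSE, params = pm),
            class = "premotor_network")
}

#' @export
print.premotor_network <- function(x, ...) {
  cat("<premotor_network:", length(x$fields), "fields,",
      length(x$W), "learned weight matrices, go =", x$go, ">\n")
  invisible(x)
}

#' Release (or reassert) the tonic go-signal inhibition
#'
#' Execution-related fields receive a tonic inhibitory bias `GP`, 10 before
#' the go signal and 0 after; preparation fields are unaffected.
#'
#' @param net a [premotor_network()].
#' @param go logical.
#' @return the network.
#' @export
set_go_signal <- function(net, go) {
  net$go <- isTRUE(go)
  net
}

gp_level <- function(net) if (net$go) 0 else net$gp

f5_names <- c("prec", "tri", "pow", "side")

#' Weighted inputs to every premotor field
#'
#' Implements the printed input sums: F2vr from the parietal direction and
#' distance codes through 3I; execution fields from their preparation
#' counterparts through 2I minus the tonic inhibition GP; F7s from AIP (the
#' direction field also from F2vrDIR); each F5s field from AIP minus the
#' cross-field inhibition `0.25 * sum` of the other three F5s fields; WRs
#' from AIP, F7sDIR and all four F5s fields (the offset radius deliberately
#' does not project to the wrist network).
#'
#' @param net a [premotor_network()].
#' @param aip `n x n` AIP activity matrix (or vector).
#' @param parietal the encoded scene from [encode_scene()].
#' @return named list of input arrays, one per field.
#' @export
compute_premotor_inputs <- function(net, aip, parietal) {
  f <- net$fields
  W <- net$W
  aip_v <- as.numeric(aip)
  gp <- gp_level(net)
  three <- net$fixed$parietal_f2; two <- net$fixed$relay
  cross <- net$fixed$f5_cross
  f5_sums <- vapply(f5_names, function(k) sum(f[[paste0("f5s_", k)]]$f), 0)
  ins <- list(
    f2vr_dir = three * parietal$dir$values,
    f2vr_rad = array(three * parietal$dist$values, dim(f$f2vr_rad$u)),
    f2d_dir  = two * f$f2vr_dir$f - gp,
    f2d_rad  = two * f$f2vr_rad$f - gp,
    f7s_dir  = array(aip_v %*% W$aip_f7dir, dim(f$f7s_dir$u)) +
      array(as.numeric(f$f2vr_dir$f) %*% W$f2_f7, dim(f$f7s_dir$u)),
    f7s_rad  = array(aip_v %*% W$aip_f7rad, dim(f$f7s_rad$u)),
    f7e_dir  = two * f$f7s_dir$f - gp,
    f7e_rad  = two * f$f7s_rad$f - gp,
    wrs = array(aip_v %*% W$aip_wr +
                  as.numeric(f$f7s_dir$f) %*% W$f7_wr +
                  Reduce(`+`, lapply(f5_names, function(k)
                    as.numeric(f[[paste0("f5s_", k)]]$f) %*%
                      W[[paste0("f5_wr_", k)]])),
                dim(f$wrs$u)),
    wre = two * f$wrs$f - gp)
  for (k in f5_names) {
    others <- sum(f5_sums[setdiff(f5_names, k)])
    ins[[paste0("f5s_", k)]] <-
      array(aip_v %*% W[[paste0("aip_f5_", k)]] - cross * others,
            dim(f[[paste0("f5s_", k)]]$u))
    ins[[paste0("f5e_", k)]] <-
      two * f[[paste0("f5s_", k)]]$f - gp
  }
  ins
}

#' Settle the premotor network on a trial's input
#'
#' Phase 1 (object visible, go signal withheld): the preparation fields
#' integrate their inputs to WTA bumps; execution fields sit at the inhibited
#' floor and are not integrated.  Phase 2 (go): the tonic inhibition is
#' released and the execution fields settle on the (now static) preparation
#' activity.
#'
#' @param net a [premotor_network()].
#' @param aip AIP activity matrix.
#' @param parietal encoded scene ([encode_scene()]).
#' @param cfg an [ag_config()] list.
#' @param dt integration step (s).
#' @param add_noise per-step field noise.
#' @return the settled network with `go = TRUE`.
#' @export
settle_premotor <- function(net, aip, parietal, cfg, dt = control_dt(cfg),
                            add_noise = TRUE) {
  pm <- net$params
  for (nm in names(net$fields)) net$fields[[nm]] <- dnf_reset(net$fields[[nm]])
  net <- set_go_signal(net, FALSE)
  f <- net$fields; W <- net$W
  aip_v <- as.numeric(aip)
  three <- net$fixed$parietal_f2; two <- net$fixed$relay
  cross <- net$fixed$f5_cross
  # input components that do not change while the scene is static are
  # computed once; only terms fed by evolving preparation fields are
  # recomputed each step (identical sums to compute_premotor_inputs())
  st <- list(
    f2vr_dir = three * parietal$dir$values,
    f2vr_rad = array(three * parietal$dist$values, dim(f$f2vr_rad$u)),
    f7s_dir  = array(aip_v %*% W$aip_f7dir, dim(f$f7s_dir$u)),
    f7s_rad  = array(aip_v %*% W$aip_f7rad, dim(f$f7s_rad$u)),
    wrs      = array(aip_v %*% W$aip_wr, dim(f$wrs$u)))
  for (k in f5_names) {
    st[[paste0("f5s_", k)]] <-
      array(aip_v %*% W[[paste0("aip_f5_", k)]],
            dim(f[[paste0("f5s_", k)]]$u))
  }
  prep <- c("f2vr_dir", "f2vr_rad", "f7s_dir", "f7s_rad",
            paste0("f5s_", f5_names), "wrs")
  n1 <- max(1L, round(pm$prep_settle / dt))
  for (step in seq_len(n1)) {
    f5_sums <- vapply(f5_names, function(k) sum(f[[paste0("f5s_", k)]]$f), 0)
    ins <- st
    ins$f7s_dir <- st$f7s_dir +
      array(as.numeric(f$f2vr_dir$f) %*% W$f2_f7, dim(f$f7s_dir$u))
    ins$wrs <- st$wrs +
      array(as.numeric(f$f7s_dir$f) %*% W$f7_wr +
              Reduce(`+`, lapply(f5_names, function(k)
                as.numeric(f[[paste0("f5s_", k)]]$f) %*%
                  W[[paste0("f5_wr_", k)]])),
            dim(f$wrs$u))
    for (k in f5_names) {
      ins[[paste0("f5s_", k)]] <- st[[paste0("f5s_", k)]] -
        cross * sum(f5_sums[setdiff(f5_names, k)])
    }
    for (nm in prep) f[[nm]] <- dnf_step(f[[nm]], ins[[nm]], dt, add_noise)
  }
  net$fields <- f
  net <- set_go_signal(net, TRUE)
  exec <- c("f2d_dir", "f2d_rad", "f7e_dir", "f7e_rad",
            paste0("f5e_", f5_names), "wre")
  ins <- compute_premotor_inputs(net, aip, parietal)  # static post-settle
  n2 <- max(1L, round(pm$exec_settle / dt))
  for (step in seq_len(n2)) {
    for (nm in exec) {
      net$fields[[nm]] <- dnf_step(net$fields[[nm]], ins[[nm]], dt, add_noise)
    }
  }
  net
}

#' REINFORCE update of one learned weight matrix
#'
#' `W <- W + alpha * rs * pre %o% exec`: Hebbian for positive reward,
#' anti-Hebbian for negative, with the execution-related activity serving as
#' the eligibility trace.
#'
#' @param W weight matrix (pre x exec).
#' @param pre,exec activity vectors.
#' @param rs scalar reinforcement signal.
#' @param alpha learning rate.
#' @return the updated matrix.
#' @export
reinforce_update <- function(W, pre, exec, rs, alpha) {
  if (rs == 0) return(W)
  W + alpha * rs * outer(as.numeric(pre), as.numeric(exec))
}

#' Apply the reward signal to every learned premotor projection
#'
#' One application per rewarded time step (the reward occupies the last
#' `n_steps` steps of a trial with static settled activities, so the updates
#' compose additively).  `scope = "wrist"` restricts learning to the F7 ->
#' wrist-rotation projection (the wrist pretraining stage); `"all"` updates
#' every learned matrix.
#'
#' @param net a [premotor_network()].
#' @param aip AIP activity matrix.
#' @param rs scalar reinforcement signal per step.
#' @param cfg an [ag_config()] list.
#' @param n_steps number of reward steps.
#' @param scope `"all"` or `"wrist"`.
#' @return the network with updated weights.
#' @export
premotor_learn <- function(net, aip, rs, cfg, n_steps = cfg$training$reward_steps,
                           scope = c("all", "wrist")) {
  scope <- match.arg(scope)
  if (rs == 0 || n_steps == 0) return(net)
  pm <- net$params
  f <- net$fields
  aip_v <- as.numeric(aip)
  eff <- function(alpha) alpha * n_steps
  # synaptic saturation: learned weights stay within +/- w_cap so the total
  # drive they deliver remains inside the fields' operating range
  cap <- if (is.null(pm$w_cap)) Inf else pm$w_cap
  clamp_all <- function(net) {
    for (nm in names(net$W)) {
      W <- net$W[[nm]]
      if (any(W > cap) || any(W < -cap)) {
        net$W[[nm]] <- pmin(pmax(W, -cap), cap)
      }
    }
    net
  }
  wre_v <- as.numeric(f$wre$f)
  net$W$f7_wr <- reinforce_update(net$W$f7_wr, as.numeric(f$f7e_dir$f), wre_v,
                                  rs, eff(pm$alpha_wr))
  if (scope == "wrist") return(clamp_all(net))
  f7e_dir_v <- as.numeric(f$f7e_dir$f)
  net$W$aip_f7dir <- reinforce_update(net$W$aip_f7dir, aip_v, f7e_dir_v,
                                      rs, eff(pm$alpha_f7))
  net$W$aip_f7rad <- reinforce_update(net$W$aip_f7rad, aip_v,
                                      as.numeric(f$f7e_rad$f), rs,
                                      eff(pm$alpha_f7))
  net$W$f2_f7 <- reinforce_update(net$W$f2_f7, as.numeric(f$f2d_dir$f),
                                  f7e_dir_v, rs, eff(pm$alpha_f7))
  net$W$aip_wr <- reinforce_update(net$W$aip_wr, aip_v, wre_v,
                                   rs, eff(pm$alpha_wr))
  for (k in f5_names) {
    ek <- as.numeric(f[[paste0("f5e_", k)]]$f)
    net$W[[paste0("aip_f5_", k)]] <-
      reinforce_update(net$W[[paste0("aip_f5_", k)]], aip_v, ek,
                       rs, eff(pm$alpha_f5))
    net$W[[paste0("f5_wr_", k)]] <-
      reinforce_update(net$W[[paste0("f5_wr_", k)]], ek, wre_v,
                       rs, eff(pm$alpha_wr))
  }
  clamp_all(net)
}
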