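#' Geometric contact detection between hand landmarks and an object
#'
#' A landmark makes contact when it lies within `contact$delta` of the object
#' surface (slight penetration is tolerated, since the surrogate has no
#' contact forces).  When landmark velocities are supplied, a landmark moving
#' away from the surface (velocity along the outward normal above a small
#' tolerance) is not counted, so brushing past an object on the way out does
#' not register.
#'
#' @param state an [arm_hand_state()], or a precomputed 3 x k landmark matrix.
#' @param object an [object_primitive()].
#' @param cfg an [ag_config()] list.
#' @param velocities optional 3 x k matrix of landmark velocities (m/s).
#' @param time contact timestamp (s) recorded in the result.
#' @return data.frame(body_part, x, y, z, time), one row per contact.
#' @export
detect_contacts <- function(state, object, cfg, velocities = NULL, time = 0) {
  lm <- if (inherits(state, "arm_hand_state")) {
    forward_kinematics(state, check_limits = FALSE)$landmarks
  } else state
  sd <- object_sdf(object, lm)
  hit <- sd <= cfg$contact$delta & sd >= -(cfg$contact$delta + 0.02)
  if (any(hit) && !is.null(velocities)) {
    for (i in which(hit)) {
      n_out <- surface_normal(object, lm[, i])
      if (sum(velocities[, i] * n_out) > 0.02 && sd[i] > 0) hit[i] <- FALSE
    }
  }
  idx <- which(hit)
  data.frame(body_part = colnames(lm)[idx],
             x = lm[1, idx], y = lm[2, idx], z = lm[3, idx],
             time = rep(time, length(idx)), row.names = NULL,
             stringsAsFactors = FALSE)
}

# outward unit normal of the object surface nearest to p (FD gradient)
surface_normal <- function(object, p) {
  h <- 1e-5
  g <- c(object_sdf(object, p + c(h, 0, 0)) - object_sdf(object, p - c(h, 0, 0)),
         object_sdf(object, p + c(0, h, 0)) - object_sdf(object, p - c(0, h, 0)),
         object_sdf(object, p + c(0, 0, h)) - object_sdf(object, p - c(0, 0, h)))
  unit(g)
}

# body-part opposition classes: thumb vs fingers, palm vs (fingers or thumb)
body_group <- function(part) {
  ifelse(grepl("^thumb", part), "thumb",
         ifelse(part == "palm", "palm", "finger"))
}

parts_oppose <- function(a, b) {
  ga <- body_group(a); gb <- body_group(b)
  (ga == "thumb" & gb == "finger") | (ga == "finger" & gb == "thumb") |
    (ga == "palm" & gb != "palm") | (gb == "palm" & ga != "palm")
}

# does the open segment p1-p2 pass through the object interior?
segment_through_interior <- function(p1, p2, object, depth = 1e-3, n = 15) {
  tt <- seq(0, 1, length.out = n)
  pts <- outer(p1, 1 - tt) + outer(p2, tt)
  min(object_sdf(object, pts)) <= -depth
}

#' Opposing contact pairs whose axis passes through the object
#'
#' The grasp-stability surrogate's core predicate: pairs of contacts from
#' distinct opposing body parts (thumb vs finger, palm vs finger or thumb)
#' whose connecting segment penetrates the object interior — an opposition
#' axis through the object.
#'
#' @param contacts a data.frame from [detect_contacts()].
#' @param object an [object_primitive()].
#' @param cfg an [ag_config()] list.
#' @return character vector of pair keys `"partA|partB"` (sorted, unique).
#' @export
opposition_pairs <- function(contacts, object, cfg) {
  n <- nrow(contacts)
  if (is.null(n) || n < 2) return(character(0))
  keys <- character(0)
  pts <- t(as.matrix(contacts[, c("x", "y", "z")]))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    a <- contacts$body_part[i]; b <- contacts$body_part[j]
    if (!parts_oppose(a, b)) next
    if (segment_through_interior(pts[, i], pts[, j], object,
                                 cfg$contact$interior_depth)) {
      keys <- c(keys, paste(sort(c(a, b)), collapse = "|"))
    }
  }
  unique(keys)
}

#' Evaluate grasp stability over a contact history
#'
#' A grasp is stable iff some opposing body-part pair keeps an opposition
#' axis through the object continuously for at least `hold_duration`
#' (default 2 s of simulation time).  The same pair must persist; losing a
#' contact resets that pair's clock.
#'
#' @param contact_history list of per-step entries, each
#'   `list(time = <s>, contacts = <data.frame>)`, in time order.
#' @param object an [object_primitive()] (its final pose).
#' @param cfg an [ag_config()] list.
#' @param hold_duration required persistence (s).
#' @return `"stable"` or `"unstable"`.
#' @export
evaluate_grasp_stability <- function(contact_history, object, cfg,
                                     hold_duration = cfg$training$hold_duration) {
  if (length(contact_history) == 0) return("unstable")
  start <- new.env(parent = emptyenv())  # pair key -> onset time
  prev <- character(0)
  for (step in contact_history) {
    keys <- opposition_pairs(step$contacts, object, cfg)
    for (k in keys) {
      if (is.null(start[[k]])) start[[k]] <- step$time
      if (step$time - start[[k]] >= hold_duration - 1e-9) return("stable")
    }
    for (k in setdiff(prev, keys)) if (!is.null(start[[k]])) rm(list = k, envir = start)
    prev <- keys
  }
  "unstable"
}

#' Displace the object after a non-grasping collision
#'
#' Surrogate for a hand-object collision knocking the object away: when
#' contacts exist with no opposition axis through the object and the hand is
#' moving faster than `speed_floor`, the object is displaced along the push
#' direction proportionally to the penetration depth, capped per step.
#' Contacts forming a stable opposition are exempt.
#'
#' @param object an [object_primitive()].
#' @param contacts a data.frame from [detect_contacts()].
#' @param hand_velocity 3-vector, velocity of the hand (m/s).
#' @param cfg an [ag_config()] list.
#' @return the (possibly displaced) `object_primitive`.
#' @export
perturb_object_on_collision <- function(object, contacts, hand_velocity, cfg) {
  if (is.null(nrow(contacts)) || nrow(contacts) == 0) return(object)
  has_opp <- length(opposition_pairs(contacts, object, cfg)) > 0
  pts <- t(as.matrix(contacts[, c("x", "y", "z")]))
  perturb_impl(object, pts, hand_velocity, has_opp, cfg)
}

perturb_impl <- function(object, pts, hand_velocity, has_opposition, cfg) {
  if (has_opposition) return(object)
  speed <- sqrt(sum(hand_velocity^2))
  if (speed <= cfg$contact$speed_floor) return(object)
  pen <- max(0, -min(object_sdf(object, pts)))
  if (pen <= 0) return(object)
  disp <- min(cfg$contact$perturb_gain * pen, cfg$contact$perturb_cap)
  object_translate(object, disp * unit(hand_velocity))
}
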