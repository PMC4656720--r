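#' Population-code specification
#'
#' A 1-, 2- or 3-D grid of units with preferred stimulus values uniformly
#' spaced over stated ranges, a shared Gaussian tuning width and an additive
#' noise level.  Because a single `sigma` applies to the summed squared
#' deviations across dimensions, the multi-dimensional Gaussian factorizes
#' into an outer product of per-dimension profiles.
#'
#' @param ranges list of length `dims`, each `c(lo, hi)`.
#' @param n integer unit count per dimension (length `dims`).
#' @param sigma tuning width (stimulus units).
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @return an object of class `"population_spec"`.
#' @export
population_spec <- function(ranges, n, sigma, noise_sd = 0) {
  if (!is.list(ranges)) ranges <- list(ranges)
  n <- as.integer(n)
  stopifnot(length(n) == length(ranges), all(n >= 2), sigma > 0, noise_sd >= 0)
  pref <- Map(function(r, k) seq(r[1], r[2], length.out = k), ranges, n)
  structure(list(dims = length(n), n = n, ranges = ranges, pref = pref,
                 sigma = sigma, noise_sd = noise_sd),
            class = "population_spec")
}

# sum of factorized Gaussian bumps; `stim` is a matrix (rows = components,
# cols = dims).  Returns an array with dim = spec$n.
pop_encode <- function(spec, stim, add_noise = TRUE) {
  vals <- array(0, dim = spec$n)
  if (!is.null(stim) && nrow(stim) > 0) {
    for (p in seq_len(nrow(stim))) {
      gs <- Map(function(pref, x) exp(-(pref - x)^2 / (2 * spec$sigma^2)),
                spec$pref, as.list(stim[p, ]))
      bump <- Reduce(function(a, b) outer(a, b), gs)
      vals <- vals + array(bump, dim = spec$n)
    }
  }
  if (add_noise && spec$noise_sd > 0) {
    vals <- vals + stats::rnorm(length(vals), 0, spec$noise_sd)
    vals[vals < 0] <- 0  # activities clipped at the zero floor
  }
  structure(list(values = vals, spec = spec), class = "population_activity")
}

as_objects <- function(objects) {
  if (inherits(objects, "object_primitive")) list(objects) else objects
}

#' Encode shoulder-centered object distance (V6A/MIP DIST population)
#'
#' One-dimensional Gaussian population code over the distance `rho_s` of each
#' object component, preferred distances uniform over the spec range.
#'
#' @param objects an [object_primitive()] or list of them.
#' @param spec a 1-D [population_spec()].
#' @param add_noise draw the additive noise term.
#' @return a `population_activity`.
#' @export
encode_distance <- function(objects, spec, add_noise = TRUE) {
  stopifnot(spec$dims == 1)
  stim <- matrix(vapply(as_objects(objects), function(o) o$sph[["rho"]], 0),
                 ncol = 1)
  pop_encode(spec, stim, add_noise)
}

#' Encode shoulder-centered object direction (V6A/MIP DIR population)
#'
#' Two-dimensional code over azimuth and elevation `(theta_s, phi_s)`.
#' @inheritParams encode_distance
#' @param spec a 2-D [population_spec()] over (azimuth, elevation).
#' @return a `population_activity`.
#' @export
encode_direction <- function(objects, spec, add_noise = TRUE) {
  stopifnot(spec$dims == 2)
  stim <- t(vapply(as_objects(objects),
                   function(o) c(o$sph[["theta"]], o$sph[["phi"]]),
                   numeric(2)))
  pop_encode(spec, stim, add_noise)
}

#' Encode main-axis orientation (cIPS AOS populations, CYL and RECT)
#'
#' Shape-gated three-dimensional codes over the components of the object's
#' main-axis unit vector: cylinders drive only the CYL population,
#' rectangular shapes only RECT; the non-matching population (and both, for
#' spheres) carries pure noise.
#'
#' @inheritParams encode_distance
#' @param cyl_spec,rect_spec 3-D [population_spec()]s over axis components.
#' @return list(cyl = , rect = ) of `population_activity`.
#' @export
encode_axis_orientation <- function(objects, cyl_spec, rect_spec,
                                    add_noise = TRUE) {
  stopifnot(cyl_spec$dims == 3, rect_spec$dims == 3)
  objs <- as_objects(objects)
  axes <- function(sel) {
    keep <- Filter(sel, objs)
    if (length(keep) == 0) return(matrix(numeric(0), ncol = 3))
    t(vapply(keep, function(o) o$main_axis, numeric(3)))
  }
  list(cyl = pop_encode(cyl_spec, axes(function(o) o$shape == "cylinder"),
                        add_noise),
       rect = pop_encode(rect_spec, axes(function(o) is_rectangular(o$shape)),
                         add_noise))
}

#' Encode visible surface normals (cIPS SOS population)
#'
#' Sum over the visible faces of each rectangular component of 3-D Gaussians
#' centered on the face-normal components.  A face is visible iff its outward
#' normal has negative dot product with the view direction.  Non-rectangular
#' objects yield pure noise.
#'
#' @inheritParams encode_distance
#' @param spec a 3-D [population_spec()] over normal components in `[-1, 1]`.
#' @param view_dir gaze direction (3-vector).
#' @return a `population_activity`.
#' @export
encode_surface_normals <- function(objects, spec, view_dir = c(0, 1, 0),
                                   add_noise = TRUE) {
  stopifnot(spec$dims == 3)
  stim <- matrix(numeric(0), ncol = 3)
  for (o in as_objects(objects)) {
    if (!is_rectangular(o$shape)) next
    fn <- o$face_normals
    vis <- colSums(fn * view_dir) < 0
    if (any(vis)) stim <- rbind(stim, t(fn[, vis, drop = FALSE]))
  }
  pop_encode(spec, stim, add_noise)
}

#' Encode object component size (cIPS size population)
#'
#' Three-dimensional Gaussian code over `(s_x, s_y, s_z)`, with sizes
#' normalized by `size_max` so the shared cIPS tuning width applies.
#'
#' @inheritParams encode_distance
#' @param spec a 3-D [population_spec()] over normalized sizes.
#' @param size_max the size (m) mapping to normalized 1.0.
#' @return a `population_activity`.
#' @export
encode_size <- function(objects, spec, size_max = 0.25, add_noise = TRUE) {
  stopifnot(spec$dims == 3)
  stim <- t(vapply(as_objects(objects), function(o) o$size / size_max,
                   numeric(3)))
  pop_encode(spec, stim, add_noise)
}

#' Build the normalized AIP input vector
#'
#' Concatenates the DIR, CYL, RECT, SOS and size activities (the distance
#' population is deliberately excluded: distance parameterizes the reach, not
#' the grasp) and scales the result to unit Euclidean norm.  An all-zero
#' concatenation is returned as the zero vector with attribute
#' `degenerate = TRUE`.
#'
#' @param dir,cyl,rect,sos,s `population_activity` objects.
#' @return numeric vector with attribute `"degenerate"`.
#' @export
build_aip_input <- function(dir, cyl, rect, sos, s) {
  parts <- list(dir, cyl, rect, sos, s)
  v <- unlist(lapply(parts, function(a) as.vector(a$values)), use.names = FALSE)
  if (any(!is.finite(v))) stop("non-finite population activity", call. = FALSE)
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) {
    attr(v, "degenerate") <- TRUE
    return(v)
  }
  v <- v / nrm
  attr(v, "degenerate") <- FALSE
  v
}

# the full parietal encoding step used by trials
parietal_specs <- function(cfg) {
  p <- cfg$parietal
  list(
    dist = population_spec(list(p$dist$range), p$dist$n, p$dist$sigma,
                           p$noise_sd),
    dir = population_spec(list(p$dir$theta_range, p$dir$phi_range),
                          p$dir$n, p$dir$sigma, p$noise_sd),
    cyl = population_spec(rep(list(p$cips$comp_range), 3), p$cips$n,
                          p$cips$sigma, p$noise_sd),
    rect = population_spec(rep(list(p$cips$comp_range), 3), p$cips$n,
                           p$cips$sigma, p$noise_sd),
    sos = population_spec(rep(list(p$cips$comp_range), 3), p$cips$n,
                          p$cips$sigma, p$noise_sd),
    s = population_spec(rep(list(p$cips$size_range), 3), p$cips$n,
                        p$cips$sigma, p$noise_sd))
}

#' Encode one scene into all parietal populations and the AIP input
#' @param objects an [object_primitive()] or list of them.
#' @param cfg an [ag_config()] list.
#' @param add_noise draw the additive noise terms.
#' @return list of `population_activity` (`dist`, `dir`, `cyl`, `rect`,
#'   `sos`, `s`) plus `aip_input`.
#' @export
encode_scene <- function(objects, cfg, add_noise = TRUE) {
  sp <- parietal_specs(cfg)
  ao <- encode_axis_orientation(objects, sp$cyl, sp$rect, add_noise)
  out <- list(
    dist = encode_distance(objects, sp$dist, add_noise),
    dir = encode_direction(objects, sp$dir, add_noise),
    cyl = ao$cyl, rect = ao$rect,
    sos = encode_surface_normals(objects, sp$sos, cfg$view_dir, add_noise),
    s = encode_size(objects, sp$s, cfg$parietal$cips$size_max, add_noise))
  out$aip_input <- build_aip_input(out$dir, out$cyl, out$rect, out$sos, out$s)
  out
}
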