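#' Graspable object primitives
#'
#' An object primitive is one of five shapes (cube, rectangular prism,
#' cylinder, sphere, flat plate) with a size triple `(s_x, s_y, s_z)` (full
#' extents, m), a shoulder-centered position and an intrinsic z-y-x Euler
#' orientation `(o_x, o_y, o_z)`.  Derived fields computed at construction:
#' the rotation matrix, the main-axis unit vector, outward face normals
#' (rectangular shapes only) and the shoulder-centered spherical pose
#' `(theta_s, phi_s, rho_s)`.
#'
#' For the cylinder the size triple is `(d, d, L)`: diameter twice, then
#' length along the local z axis.  For the sphere all three entries equal the
#' diameter.
#'
#' @param shape one of `"cube"`, `"rectangular_prism"`, `"cylinder"`,
#'   `"sphere"`, `"plate"`.
#' @param size numeric 3-vector of positive extents (m).
#' @param position numeric 3-vector, shoulder-centered (m).
#' @param orientation numeric 3-vector of Euler angles (rad).
#' @return an object of class `"object_primitive"`.
#' @export
object_primitive <- function(shape, size, position,
                             orientation = c(0, 0, 0)) {
  shape <- match.arg(shape, c("cube", "rectangular_prism", "cylinder",
                              "sphere", "plate"))
  size <- as.numeric(size); position <- as.numeric(position)
  orientation <- as.numeric(orientation)
  stopifnot(length(size) == 3, length(position) == 3, length(orientation) == 3)
  if (any(size <= 0)) stop("object sizes must be strictly positive", call. = FALSE)
  R <- euler_matrix(orientation)
  obj <- list(shape = shape, size = size, position = position,
              orientation = orientation, rot = R)
  obj$main_axis <- unit(R %*% local_main_axis(shape, size))[, 1]
  obj$face_normals <- if (is_rectangular(shape)) {
    cbind(R, -R)  # outward unit normals of the 6 faces, world frame
  } else {
    matrix(numeric(0), nrow = 3)
  }
  sph <- cart_to_sph(position)
  obj$sph <- sph
  class(obj) <- "object_primitive"
  obj
}

is_rectangular <- function(shape) {
  shape %in% c("cube", "rectangular_prism", "plate")
}

local_main_axis <- function(shape, size) {
  if (shape %in% c("cylinder", "sphere")) return(c(0, 0, 1))
  ax <- diag(3)[, which.max(size)]
  ax
}

#' @export
print.object_primitive <- function(x, ...) {
  cat(sprintf("<%s  size %.3f x %.3f x %.3f m  at (%.2f, %.2f, %.2f)>\n",
              x$shape, x$size[1], x$size[2], x$size[3],
              x$position[1], x$position[2], x$position[3]))
  invisible(x)
}

#' Signed distance from points to an object surface
#'
#' Negative inside, positive outside, zero on the surface.
#'
#' @param obj an [object_primitive()].
#' @param pts numeric 3-vector or 3 x n matrix of points (world frame, m).
#' @return numeric vector of signed distances (m).
#' @export
object_sdf <- function(obj, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 3)
  q <- crossprod(obj$rot, pts - obj$position)  # local frame
  h <- obj$size / 2
  switch(obj$shape,
    sphere = sqrt(colSums(q^2)) - h[1],
    cylinder = {
      dr <- sqrt(q[1, ]^2 + q[2, ]^2) - h[1]
      dz <- abs(q[3, ]) - h[3]
      out_r <- pmax(dr, 0); out_z <- pmax(dz, 0)
      sqrt(out_r^2 + out_z^2) + pmin(pmax(dr, dz), 0)
    },
    { # box-like shapes
      d <- abs(q) - h
      out <- pmax(d, 0)
      sqrt(colSums(out^2)) + pmin(apply(d, 2, max), 0)
    })
}

#' Translate an object primitive, recomputing derived fields
#' @param obj an [object_primitive()].
#' @param delta numeric 3-vector displacement (m).
#' @return the displaced `object_primitive`.
#' @export
object_translate <- function(obj, delta) {
  object_primitive(obj$shape, obj$size, obj$position + as.numeric(delta),
                   obj$orientation)
}

#' Sample a random object for a trial
#'
#' Shape uniform over the configured set; position uniform in the spherical
#' pose window (all within reach); orientation uniform within
#' `+/- orientation_max` per Euler angle; sizes uniform in per-shape ranges.
#' With `novel = TRUE` the pose window switches to the disjoint probe window
#' and sizes are drawn above the training upper bounds, so probe objects are
#' outside the training ranges by construction.
#'
#' @param cfg an [ag_config()] list.
#' @param rng an [ag_rng()] object (stream `"sampling"`), or `NULL` to use
#'   the current global RNG.
#' @param novel logical; draw from the probe ranges instead.
#' @return an [object_primitive()] with attribute `"novel"`.
#' @export
sample_object <- function(cfg, rng = NULL, novel = FALSE) {
  draw <- function() sample_object_impl(cfg, novel)
  obj <- if (is.null(rng)) draw() else with_stream(rng, "sampling", draw())
  attr(obj, "novel") <- novel
  obj
}

sample_object_impl <- function(cfg, novel) {
  oc <- cfg$objects
  if (length(oc$shapes) == 0) stop("empty shape set", call. = FALSE)
  shape <- if (length(oc$shapes) == 1) oc$shapes else sample(oc$shapes, 1)
  rng_u <- function(r) stats::runif(1, r[1], r[2])
  if (novel) {
    theta <- rng_u(oc$novel$azimuth_range)
    phi   <- rng_u(oc$novel$elevation_range)
    rho   <- rng_u(oc$novel$rho_range)
  } else {
    theta <- rng_u(oc$azimuth_range)
    phi   <- rng_u(oc$elevation_range)
    rho   <- rng_u(oc$rho_range)
  }
  # novel sizes sit outside the training interval: above it when the scale
  # exceeds 1, below it otherwise
  s_out <- function(r) {
    sc <- oc$novel$size_scale
    if (sc >= 1) stats::runif(1, r[2], r[2] * sc) else stats::runif(1, r[1] * sc, r[1])
  }
  s_in <- function(r) if (novel) s_out(r) else rng_u(r)
  sz <- oc$size[[shape]]
  size <- switch(shape,
    cube   = rep(s_in(sz$side), 3),
    sphere = rep(s_in(sz$diam), 3),
    rectangular_prism = c(s_in(sz$cross), s_in(sz$cross), s_in(sz$length)),
    cylinder = { d <- s_in(sz$diam); c(d, d, s_in(sz$length)) },
    plate  = { s <- s_in(sz$side); c(s, s_in(sz$side), s_in(sz$thick)) })
  orientation <- stats::runif(3, -oc$orientation_max, oc$orientation_max)
  object_primitive(shape, size, sph_to_cart(theta, phi, rho), orientation)
}
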