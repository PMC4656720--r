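#' Dynamic neural fields (winner-take-all parameter selectors)
#'
#' Each field is a 1-, 2- or 3-D grid of leaky-integrator units with a
#' sigmoidal firing rate, recurrently coupled through a kernel that is a
#' Gaussian center peak on a uniformly negative background.  The kernel
#' spans twice the population per dimension, so the inhibitory background
#' reaches every unit pair and competition is global: the field settles on a
#' single bump centered on the strongest input peak.
#'
#' @param dims field dimensionality (1, 2 or 3).
#' @param n units per dimension (scalar or length-`dims`).
#' @param ranges list of `c(lo, hi)` preferred-value ranges per dimension.
#' @param params the `dnf` block of an [ag_config()].
#' @return an object of class `"dnf_field"` with membrane potentials `u`,
#'   firing rates `f`, preferred values `pref` and cached convolution
#'   matrices.
#' @export
dnf_field <- function(dims, n, ranges, params) {
  if (length(n) == 1) n <- rep(n, dims)
  n <- as.integer(n)
  if (!is.list(ranges)) ranges <- list(ranges)
  stopifnot(length(n) == dims, length(ranges) == dims, all(n >= 2))
  pref <- Map(function(r, k) seq(r[1], r[2], length.out = k), ranges, n)
  u <- array(params$h, dim = if (dims == 1) c(n, 1) else n)
  fld <- list(dims = dims, n = n, pref = pref, params = params,
              u = u, f = dnf_sigmoid(u, params),
              G = lapply(n, function(k) gauss_mat(k, params$sigma)))
  class(fld) <- "dnf_field"
  fld
}

dnf_sigmoid <- function(u, params) {
  1 / (1 + exp(-params$beta * (u - params$u0)))
}

gauss_mat <- function(n, sigma) {
  idx <- seq_len(n)
  exp(-outer(idx, idx, `-`)^2 / (2 * sigma^2))
}

#' Explicit winner-take-all convolution kernel
#'
#' The kernel on the doubled grid (size `2N` per dimension, center at index
#' `N`): `w_excite * exp(-sum(d^2) / (2 sigma^2)) - w_inhibit` for
#' displacement `d`.  [dnf_step()] applies it through the algebraically
#' identical separable form (Gaussian convolution minus global inhibition);
#' this function exposes the kernel itself.
#'
#' @param dims kernel dimensionality.
#' @param n population size per dimension (scalar).
#' @param params the `dnf` block of an [ag_config()].
#' @return array with `2n` entries per dimension.
#' @export
dnf_kernel <- function(dims, n, params) {
  stopifnot(n >= 2)
  d <- seq_len(2 * n) - n  # displacement, center at index n
  g1 <- exp(-d^2 / (2 * params$sigma^2))
  g <- Reduce(function(a, b) outer(a, b), rep(list(g1), dims))
  params$w_excite * g - params$w_inhibit
}

# recurrent drive f * W using separability: w_e * gaussian_conv(f) - w_i * sum(f)
dnf_recurrent <- function(fld) {
  p <- fld$params
  f <- fld$f
  conv <- switch(fld$dims,
    `1` = fld$G[[1]] %*% f,
    `2` = fld$G[[1]] %*% f %*% t(fld$G[[2]]),
    `3` = {
      n <- fld$n
      m <- matrix(f, n[1], n[2] * n[3])
      m <- fld$G[[1]] %*% m                     # dim 1
      a <- array(m, n)
      m2 <- matrix(aperm(a, c(2, 1, 3)), n[2], n[1] * n[3])
      a <- aperm(array(fld$G[[2]] %*% m2, c(n[2], n[1], n[3])), c(2, 1, 3))
      m3 <- matrix(aperm(a, c(3, 1, 2)), n[3], n[1] * n[2])
      aperm(array(fld$G[[3]] %*% m3, c(n[3], n[1], n[2])), c(2, 3, 1))
    })
  array(p$w_excite * conv - p$w_inhibit * sum(f), dim = dim(fld$u))
}

#' One explicit-Euler step of the field dynamics
#'
#' `tau du/dt = -u + h + IN + f * W + noise`, then `f = sigmoid(u)`.
#'
#' @param fld a [dnf_field()].
#' @param input weighted input `IN` (array matching the field, or scalar).
#' @param dt time step (s); must satisfy `dt <= tau / 2`.
#' @param add_noise draw the per-unit noise term.
#' @return the updated field.
#' @export
dnf_step <- function(fld, input, dt, add_noise = TRUE) {
  p <- fld$params
  if (dt > p$tau / 2 + 1e-12) stop("dt exceeds tau/2 stability bound", call. = FALSE)
  drive <- -fld$u + p$h + input + dnf_recurrent(fld)
  if (add_noise && p$noise_sd > 0) {
    drive <- drive + stats::rnorm(length(fld$u), 0, p$noise_sd)
  }
  fld$u <- fld$u + (dt / p$tau) * drive
  if (any(!is.finite(fld$u))) stop("field potentials diverged", call. = FALSE)
  fld$f <- dnf_sigmoid(fld$u, p)
  fld
}

#' Settle a field under a fixed input
#' @param fld a [dnf_field()].
#' @param input weighted input array (or scalar).
#' @param duration settling time (s).
#' @param dt integration step (s).
#' @param add_noise draw per-step noise.
#' @return the settled field.
#' @export
dnf_settle <- function(fld, input, duration, dt, add_noise = TRUE) {
  for (k in seq_len(max(1L, round(duration / dt)))) {
    fld <- dnf_step(fld, input, dt, add_noise)
  }
  fld
}

# reset potentials to baseline between trials
dnf_reset <- function(fld) {
  fld$u[] <- fld$params$h
  fld$f <- dnf_sigmoid(fld$u, fld$params)
  fld
}
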