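#' The AIP affordance map: a reward-modulated self-organizing map
#'
#' A toroidal `n x n` grid (default 40 x 40) of units, each holding a weight
#' vector the length of the parietal input vector `I`.  Unit activity is the
#' inner product `W(i,j) . I` plus noise.  Competitive learning moves the
#' best-matching unit (BMU) and its toroidal neighborhood toward `I`; both
#' the neighborhood radius and the learning rate decay exponentially over
#' training epochs and are expanded additively by the global reinforcement
#' signal, so rewarded inputs recruit more map territory.
#'
#' @param cfg an [ag_config()] list.
#' @param input_dim length of the input vector.
#' @param rng an [ag_rng()] for weight initialization (stream `"init"`),
#'   or `NULL` for the global RNG.
#' @return an object of class `"som_state"`: `W` (`n^2 x input_dim` matrix,
#'   row-major over the grid with column-index fastest), `n`, `epoch`,
#'   and the `r0`, `lambda`, `alpha0`, `noise_sd` parameters.
#' @export
som_state <- function(cfg, input_dim, rng = NULL) {
  s <- cfg$som
  init <- function() matrix(stats::runif(s$n^2 * input_dim, 0, s$init_max),
                            nrow = s$n^2)
  W <- if (is.null(rng)) init() else with_stream(rng, "init", init())
  # the decay constant lives on the trial axis, so it shrinks with the run
  # scale just as the stage lengths do
  structure(list(W = W, w2 = rowSums(W^2), n = s$n, epoch = 0L, r0 = s$r0,
                 lambda = s$lambda / cfg$scale, alpha0 = s$alpha0,
                 noise_sd = s$noise_sd, input_dim = input_dim),
            class = "som_state")
}

#' @export
print.som_state <- function(x, ...) {
  cat(sprintf("<som_state %d x %d, input dim %d, epoch %d>\n",
              x$n, x$n, x$input_dim, x$epoch))
  invisible(x)
}

flat_to_ij <- function(idx, n) c((idx - 1) %% n + 1, (idx - 1) %/% n + 1)
ij_to_flat <- function(i, j, n) (j - 1) * n + i

#' AIP unit activities for an input vector
#'
#' `AIP(i, j) = W(i, j) . I + noise`.
#'
#' @param som a [som_state()].
#' @param I input vector (unit norm or degenerate zero).
#' @param add_noise draw the additive Gaussian noise term.
#' @return `n x n` activity matrix.
#' @export
aip_activity <- function(som, I, add_noise = TRUE) {
  a <- as.numeric(som$W %*% as.numeric(I))
  if (add_noise && som$noise_sd > 0) {
    a <- a + stats::rnorm(length(a), 0, som$noise_sd)
  }
  matrix(a, som$n, som$n)
}

#' Best matching unit
#'
#' Argmin over units of the Euclidean distance between `I` and the unit's
#' weight vector; ties break to the lowest flat (column-major) index.
#' A degenerate (all-zero) input yields `NULL`, signalling no update.
#'
#' @param som a [som_state()].
#' @param I input vector.
#' @return `c(i, j)` grid index, or `NULL` for degenerate input.
#' @export
find_bmu <- function(som, I, WI = NULL) {
  I <- as.numeric(I)
  if (sum(I^2) == 0) return(NULL)
  if (is.null(WI)) WI <- as.numeric(som$W %*% I)
  d2 <- som$w2 - 2 * WI + sum(I^2)  # cached squared row norms
  flat_to_ij(which.min(d2), som$n)  # which.min takes the lowest index on ties
}

# toroidal Euclidean index distance from every unit to (bi, bj)
toroidal_beta <- function(n, bi, bj) {
  dx <- abs(seq_len(n) - bi); dx <- pmin(dx, n - dx)
  dy <- abs(seq_len(n) - bj); dy <- pmin(dy, n - dy)
  sqrt(outer(dx^2, dy^2, `+`))
}

#' Truncated Gaussian neighborhood function
#'
#' `Theta = exp(-beta^2 / (2 r^2))` for toroidal index distance `beta < r`,
#' zero otherwise.  At `r = 0` the limit convention applies: 1 at the BMU,
#' 0 elsewhere.
#'
#' @param som a [som_state()] (supplies the grid size).
#' @param bmu `c(i, j)` best-matching-unit index.
#' @param r neighborhood radius (grid-index units, >= 0).
#' @return `n x n` matrix of Theta values in `[0, 1]`.
#' @export
som_neighborhood <- function(som, bmu, r) {
  stopifnot(r >= 0)
  beta <- toroidal_beta(som$n, bmu[1], bmu[2])
  if (r == 0) return((beta == 0) * 1)
  theta <- exp(-beta^2 / (2 * r^2))
  theta[beta >= r] <- 0
  theta
}

#' Neighborhood radius at epoch T
#'
#' `r(t, T) = r0 exp(-T / lambda) + rs(t)`: exponential decay over training,
#' expanded additively (in grid-index units) by the reinforcement signal.
#'
#' @param som a [som_state()].
#' @param rs reinforcement signal (>= 0 contribution used here).
#' @param epoch training epoch; defaults to the map's counter.
#' @return radius (grid-index units).
#' @export
som_radius <- function(som, rs = 0, epoch = som$epoch) {
  som$r0 * exp(-epoch / som$lambda) + max(rs, 0)
}

#' Learning rate at epoch T
#'
#' `alpha(t, T) = alpha0 exp(-T / lambda) + rs(t)` (dimensionless).
#' @inheritParams som_radius
#' @return learning rate.
#' @export
som_learning_rate <- function(som, rs = 0, epoch = som$epoch) {
  som$alpha0 * exp(-epoch / som$lambda) + max(rs, 0)
}

#' One competitive-learning update of the affordance map
#'
#' Moves every unit's weights toward the input in proportion to
#' `Theta(i, j) * alpha`: `W <- W + Theta alpha (I - W)`.  The epoch counter
#' advances by one (one update per trial).  Degenerate input leaves the map
#' unchanged except for the epoch advance.
#'
#' @param som a [som_state()].
#' @param I input vector.
#' @param rs reinforcement signal applied to both radius and rate.
#' @return the updated `som_state`.
#' @export
som_update <- function(som, I, rs = 0) {
  I <- as.numeric(I)
  WI <- if (sum(I^2) > 0) as.numeric(som$W %*% I) else NULL
  bmu <- find_bmu(som, I, WI)
  if (!is.null(bmu)) {
    r <- som_radius(som, rs)
    alpha <- som_learning_rate(som, rs)
    theta <- som_neighborhood(som, bmu, r)
    g <- as.vector(theta) * alpha          # per-unit step size
    idx <- which(g > 0)
    if (length(idx)) {
      gi <- pmin(g[idx], 1)                # full step at most
      som$W[idx, ] <- som$W[idx, , drop = FALSE] * (1 - gi) + outer(gi, I)
      # ||(1-g) w + g I||^2 from cached quantities (no full-matrix pass)
      som$w2[idx] <- (1 - gi)^2 * som$w2[idx] +
        2 * gi * (1 - gi) * WI[idx] + gi^2 * sum(I^2)
    }
  }
  som$epoch <- som$epoch + 1L
  som
}
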