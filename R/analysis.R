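#' Preference index of a unit over stimulus categories
#'
#' `PI = (n - sum_i r_i / r_pref) / (n - 1)` where `r_i` is the unit's mean
#' activity for category `i`, `r_pref` the largest of them and `n` the number
#' of categories: 0 for a unit responding equally to all categories, 1 for a
#' unit responding to exactly one.
#'
#' @param r numeric vector of per-category mean activities (n >= 2).
#' @return PI in `[0, 1]`, or `NA` when `r_pref <= 0` (unit excluded).
#' @export
preference_index <- function(r) {
  n <- length(r)
  if (n < 2) stop("preference index needs at least two categories", call. = FALSE)
  r_pref <- max(r)
  if (!is.finite(r_pref) || r_pref <= 0) return(NA_real_)
  (n - sum(r) / r_pref) / (n - 1)
}

# vectorized PI over a categories x units matrix
pi_units <- function(r_mat) {
  n <- nrow(r_mat)
  r_pref <- apply(r_mat, 2, max)
  pi <- (n - colSums(r_mat) / r_pref) / (n - 1)
  pi[!is.finite(r_pref) | r_pref <= 0] <- NA_real_
  pi
}

#' Classify a preference index into selectivity classes
#'
#' Highly selective above 0.75, non-selective below 0.25, moderately
#' selective between the two (boundary values inclusive on the moderate
#' side).
#'
#' @param pi numeric vector of preference indices in `[0, 1]`.
#' @return factor with levels `"non"`, `"moderate"`, `"high"`.
#' @export
classify_selectivity <- function(pi) {
  cls <- ifelse(is.na(pi), NA_character_,
                ifelse(pi > 0.75, "high",
                       ifelse(pi < 0.25, "non", "moderate")))
  factor(cls, levels = c("non", "moderate", "high"))
}

category_means <- function(act, categories) {
  cats <- sort(unique(categories))
  r <- do.call(rbind, lapply(cats, function(cc)
    colMeans(act[categories == cc, , drop = FALSE])))
  rownames(r) <- as.character(cats)
  r
}

#' Blockwise selectivity time course of the affordance map
#'
#' Evaluates each unit's shape preference index in consecutive trial blocks
#' (the activity at decode time, with whatever noise was present), and
#' summarizes the population per block: class counts and the max / mean /
#' min PI.  Blocks missing a shape category are computed over the categories
#' present (with `n` adjusted) and flagged.
#'
#' @param records trial-record data.frame (needs `shape`).
#' @param aip trials x units activity matrix aligned with `records`.
#' @param block block size in trials (default 500).
#' @return list: `blocks` summary data.frame, `pi` units x blocks PI matrix.
#' @export
selectivity_timecourse <- function(records, aip, block = 500) {
  stopifnot(nrow(records) == nrow(aip))
  n_tr <- nrow(records)
  idx <- ceiling(seq_len(n_tr) / block)
  nb <- max(idx)
  pim <- matrix(NA_real_, ncol(aip), nb)
  out <- vector("list", nb)
  n_shapes_total <- length(unique(records$shape))
  for (b in seq_len(nb)) {
    rows <- which(idx == b)
    r <- category_means(aip[rows, , drop = FALSE], records$shape[rows])
    pi <- pi_units(r)
    pim[, b] <- pi
    cls <- classify_selectivity(pi)
    out[[b]] <- data.frame(
      block = b, first_trial = min(rows), last_trial = max(rows),
      n_units = length(pi),
      n_high = sum(cls == "high", na.rm = TRUE),
      n_moderate = sum(cls == "moderate", na.rm = TRUE),
      n_non = sum(cls == "non", na.rm = TRUE),
      n_excluded = sum(is.na(pi)),
      pi_max = max(pi, na.rm = TRUE), pi_mean = mean(pi, na.rm = TRUE),
      pi_min = min(pi, na.rm = TRUE),
      categories_missing = nrow(r) < n_shapes_total)
  }
  list(blocks = do.call(rbind, out), pi = pim)
}

pi_feature_names <- c("shape", "phi_s", "theta_s", "o_x", "o_y", "o_z",
                      "s_x", "s_y", "s_z")

#' Per-unit preference indices over every object feature
#'
#' Computes the PI of each unit for object shape and for each continuous
#' feature (shoulder-centered direction angles, orientation and size
#' components), the latter discretized into equal-width bins over the
#' sampled range.
#'
#' @param records trial-record data.frame.
#' @param aip trials x units activity matrix.
#' @param bins number of equal-width bins for continuous features.
#' @return units x 9 matrix of PIs (columns as in the feature list).
#' @export
feature_pi_panel <- function(records, aip, bins = 5) {
  stopifnot(nrow(records) == nrow(aip))
  out <- matrix(NA_real_, ncol(aip), length(pi_feature_names),
                dimnames = list(NULL, pi_feature_names))
  for (ft in pi_feature_names) {
    cats <- if (ft == "shape") {
      records$shape
    } else {
      v <- records[[ft]]
      as.integer(cut(v, breaks = seq(min(v), max(v), length.out = bins + 1),
                     include.lowest = TRUE))
    }
    out[, ft] <- pi_units(category_means(aip, cats))
  }
  out
}

#' Per-unit linear model of activity on z-scored object features
#'
#' Ordinary least squares of each unit's activity on the z-scored object
#' features (shape entered as its z-scored integer code), fitted jointly for
#' all units from one QR decomposition.  Collinear columns are dropped and
#' flagged.
#'
#' @param records trial-record data.frame.
#' @param aip trials x units activity matrix.
#' @return list: `coef` (features x units), `r_squared` (per unit),
#'   `dropped` (names of any dropped columns).
#' @export
linear_feature_fit <- function(records, aip) {
  stopifnot(nrow(records) == nrow(aip))
  X <- cbind(shape = as.integer(factor(records$shape)),
             as.matrix(records[, c("phi_s", "theta_s", "o_x", "o_y", "o_z",
                                   "s_x", "s_y", "s_z")]))
  if (nrow(X) < 10 * (ncol(X) + 1)) {
    stop("need at least 10x more trials than features", call. = FALSE)
  }
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 1e-12
  Xz <- scale(X[, keep, drop = FALSE])
  qrX <- qr(cbind(`(Intercept)` = 1, Xz))
  dropped <- colnames(X)[!keep]
  if (qrX$rank < ncol(Xz) + 1) {
    used <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- c(dropped,
                 setdiff(colnames(cbind(1, Xz)), colnames(cbind(1, Xz))[used]))
    Xz <- Xz[, used[used > 1] - 1, drop = FALSE]
    qrX <- qr(cbind(`(Intercept)` = 1, Xz))
  }
  cf <- qr.coef(qrX, aip)
  fitted <- qr.fitted(qrX, aip)
  ssr <- colSums((aip - fitted)^2)
  sst <- colSums(scale(aip, scale = FALSE)^2)
  r2 <- ifelse(sst > 0, 1 - ssr / sst, NA_real_)
  list(coef = cf[-1, , drop = FALSE], r_squared = r2, dropped = dropped)
}

#' Blocked success-rate curve
#'
#' Fraction of successful trials in consecutive blocks of `window` trials.
#'
#' @param records trial-record data.frame (needs `success`).
#' @param window block size in trials.
#' @return data.frame(block, first_trial, n, rate).
#' @export
success_rate_curve <- function(records, window = 500) {
  n <- nrow(records)
  if (is.null(n) || n == 0) {
    return(data.frame(block = integer(0), first_trial = integer(0),
                      n = integer(0), rate = numeric(0)))
  }
  idx <- ceiling(seq_len(n) / window)
  do.call(rbind, lapply(unique(idx), function(b) {
    rows <- idx == b
    data.frame(block = b, first_trial = min(which(rows)), n = sum(rows),
               rate = mean(records$success[rows]))
  }))
}
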