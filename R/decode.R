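#' Center-of-mass decoding of a population/field activity
#'
#' Activity-weighted mean of the preferred values per dimension, restricted
#' to units with activity at or above the threshold `xi` (noise in small
#' populations otherwise biases the estimate).  Returns `NULL` (a no-decode
#' signal) when no unit passes the threshold.
#'
#' @param f activity array (1-, 2- or 3-D).
#' @param pref list of per-dimension preferred-value vectors.
#' @param xi inclusion threshold.
#' @return numeric vector of decoded values (length = dims), or `NULL`.
#' @export
decode_center_of_mass <- function(f, pref, xi = 0.01) {
  f <- as.array(f)
  if (length(pref) == 1 && length(dim(f)) > 1) dim(f) <- length(f)
  mask <- f >= xi
  if (!any(mask)) return(NULL)
  fm <- f * mask
  tot <- sum(fm)
  dims <- length(pref)
  vapply(seq_len(dims), function(d) {
    sum(apply(fm, d, sum) * pref[[d]]) / tot
  }, 0)
}

#' Select the virtual-finger combination and maximum aperture
#'
#' Inter-field competition: the F5 execution field with the highest peak
#' firing wins (ties break in the order precision, tripod, power, side);
#' intra-field competition: the aperture is the 1-D center-of-mass decode of
#' the winning field.  No field above threshold is a no-grasp signal.
#'
#' @param net a settled [premotor_network()].
#' @param xi decode threshold.
#' @return list(`vf`, `aperture`), or `NULL`.
#' @export
select_vf <- function(net, xi = 0.01) {
  peaks <- vapply(f5_names, function(k)
    max(net$fields[[paste0("f5e_", k)]]$f), 0)
  if (all(peaks < xi)) return(NULL)
  win <- f5_names[which.max(peaks)]   # which.max: lowest index on ties
  fld <- net$fields[[paste0("f5e_", win)]]
  ap <- decode_center_of_mass(fld$f, fld$pref, xi)
  vf_full <- c(prec = "precision", tri = "tripod", pow = "power",
               side = "side")[[win]]
  list(vf = vf_full, aperture = as.numeric(ap))
}

#' Decode the full grasp plan from the settled execution fields
#'
#' @param net a settled [premotor_network()].
#' @param cfg an [ag_config()] list.
#' @return an object of class `"grasp_plan"` with `object_center` (theta,
#'   phi, rho), `reach_offset` (theta, phi, rho), `wrist` (wr_x, wr_y, wr_z),
#'   `vf`, `aperture`; or `NULL` when any required field fails to decode.
#' @export
decode_grasp_plan <- function(net, cfg) {
  xi <- cfg$motor$xi
  f <- net$fields
  dc <- function(nm) decode_center_of_mass(f[[nm]]$f, f[[nm]]$pref, xi)
  ctr_dir <- dc("f2d_dir"); ctr_rad <- dc("f2d_rad")
  off_dir <- dc("f7e_dir"); off_rad <- dc("f7e_rad")
  wr <- dc("wre")
  vf <- select_vf(net, xi)
  if (is.null(ctr_dir) || is.null(ctr_rad) || is.null(off_dir) ||
      is.null(off_rad) || is.null(wr) || is.null(vf)) {
    return(NULL)
  }
  structure(list(
    object_center = c(theta = ctr_dir[1], phi = ctr_dir[2], rho = ctr_rad),
    reach_offset = c(theta = off_dir[1], phi = off_dir[2], rho = off_rad),
    wrist = c(wr_x = wr[1], wr_y = wr[2], wr_z = wr[3]),
    vf = vf$vf, aperture = min(1, max(0, vf$aperture))),
    class = "grasp_plan")
}

#' @export
print.grasp_plan <- function(x, ...) {
  cat(sprintf("<grasp_plan %s grasp, aperture %.2f>\n", x$vf, x$aperture))
  cat(sprintf("  center (th, ph, rho): %.2f %.2f %.3f  offset: %.2f %.2f %.3f\n",
              x$object_center[1], x$object_center[2], x$object_center[3],
              x$reach_offset[1], x$reach_offset[2], x$reach_offset[3]))
  cat(sprintf("  wrist: %.2f %.2f %.2f\n", x$wrist[1], x$wrist[2], x$wrist[3]))
  invisible(x)
}
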