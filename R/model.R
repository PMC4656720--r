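#' Construct a fresh grasp-learning model
#'
#' Bundles everything a training run needs: the configuration, the named RNG
#' substreams, the AIP affordance map, the premotor network, and the trial
#' log.  Stages must then be run in order with [run_stage()]:
#' `"aip"` pretraining, `"wrist"` pretraining, `"grasp"` training.
#'
#' @param cfg an [ag_config()] list.
#' @return an object of class `"grasp_model"`.
#' @export
grasp_model <- function(cfg = ag_config()) {
  rng <- ag_rng(cfg$seed)
  dim_in <- aip_input_dim(cfg)
  structure(list(
    cfg = cfg, rng = rng,
    som = som_state(cfg, dim_in, rng),
    net = premotor_network(cfg, rng),
    stages_done = character(0),
    log = list(records = NULL, aip = NULL),
    version = 1L),
    class = "grasp_model")
}

#' Length of the AIP input vector for a configuration
#' @param cfg an [ag_config()] list.
#' @return integer (DIR + CYL + RECT + SOS + S unit counts; DIST excluded).
#' @export
aip_input_dim <- function(cfg) {
  p <- cfg$parietal
  as.integer(prod(p$dir$n) + 4 * prod(p$cips$n))
}

#' @export
print.grasp_model <- function(x, ...) {
  n_rec <- if (is.null(x$log$records)) 0 else nrow(x$log$records)
  cat("<grasp_model>\n")
  cat("  seed:", x$cfg$seed, " scale:", x$cfg$scale, "\n")
  cat("  affordance map:", x$som$n, "x", x$som$n,
      "units, epoch", x$som$epoch, "\n")
  cat("  stages completed:",
      if (length(x$stages_done)) paste(x$stages_done, collapse = ", ")
      else "none", "\n")
  cat("  logged trials:", n_rec, "\n")
  invisible(x)
}

#' @export
summary.grasp_model <- function(object, ...) {
  r <- object$log$records
  print(object)
  if (!is.null(r)) {
    for (st in unique(r$stage)) {
      sub <- r[r$stage == st, ]
      cat(sprintf("  %-5s stage: %d trials", st, nrow(sub)))
      if (st == "grasp") {
        cat(sprintf(", success rate %.1f%% (last half %.1f%%)",
                    100 * mean(sub$success),
                    100 * mean(sub$success[seq(ceiling(nrow(sub) / 2),
                                               nrow(sub))])))
      }
      if (st == "wrist") {
        cat(sprintf(", palm-contact rate %.1f%%", 100 * mean(sub$palm_contact)))
      }
      cat("\n")
    }
  }
  invisible(object)
}
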