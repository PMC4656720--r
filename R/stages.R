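#' Run a training stage
#'
#' Executes the stage's trials under the trial protocol: the object is
#' refreshed every `object_refresh` trials; stage lengths are divided by the
#' run scale.  Stages must run in order (AIP pretraining, wrist-rotation
#' pretraining, grasp training).  The wrist stage stops early once the
#' palm-contact rate over a sliding window exceeds the configured criterion
#' (the stage's stated purpose — most attempts make at least transient palm
#' contact — is then met).  During grasp training, once the novel-probe
#' onset is passed, each object refresh draws a probe object (disjoint
#' pose/size ranges, same shapes) with probability 1/2; probe trials are
#' flagged `novel` in the records.
#'
#' @param model a [grasp_model()].
#' @param stage `"aip"`, `"wrist"` or `"grasp"`.
#' @param n_trials stage length before scaling; defaults from the config.
#' @param novel_probe enable the mid-training novel-object probe
#'   (grasp stage only).
#' @param progress print a line every 100 trials.
#' @return the updated model with appended trial log.
#' @export
run_stage <- function(model, stage = c("aip", "wrist", "grasp"),
                      n_trials = NULL, novel_probe = TRUE, progress = FALSE) {
  stage <- match.arg(stage)
  cfg <- model$cfg
  prereq <- switch(stage, aip = character(0), wrist = "aip",
                   grasp = c("aip", "wrist"))
  if (!all(prereq %in% model$stages_done)) {
    stop("training stages must run in order (missing: ",
         paste(setdiff(prereq, model$stages_done), collapse = ", "), ")",
         call. = FALSE)
  }
  if (is.null(n_trials)) {
    n_trials <- switch(stage, aip = cfg$training$n_aip,
                       wrist = cfg$training$n_wrist,
                       grasp = cfg$training$n_grasp)
  }
  n <- max(0L, as.integer(round(n_trials / cfg$scale)))
  if (n == 0L) {
    model$stages_done <- union(model$stages_done, stage)
    return(model)
  }
  novel_onset <- if (stage == "grasp" && novel_probe) {
    ceiling(cfg$training$novel_fraction * n)
  } else Inf
  start_idx <- if (is.null(model$log$records)) 0L else max(model$log$records$trial)
  recs <- vector("list", n)
  aip_rows <- matrix(NA_real_, n, cfg$som$n^2)
  object <- NULL
  palm_window <- logical(0)
  for (k in seq_len(n)) {
    if (is.null(object) || (k - 1) %% cfg$training$object_refresh == 0) {
      novel <- k > novel_onset &&
        with_stream(model$rng, "sampling", stats::runif(1)) < 0.5
      object <- sample_object(cfg, model$rng, novel = novel)
    }
    out <- run_trial(model, object, stage, trial = start_idx + k)
    model <- out$model
    recs[[k]] <- out$record
    aip_rows[k, ] <- out$aip
    if (stage == "wrist") {
      palm_window <- c(palm_window, out$record$palm_contact)
      w <- max(1L, as.integer(round(cfg$training$wrist_stop_window / cfg$scale)))
      if (length(palm_window) > w) {
        palm_window <- palm_window[(length(palm_window) - w + 1):length(palm_window)]
      }
      if (length(palm_window) == w &&
          mean(palm_window) > cfg$training$wrist_stop_rate) {
        recs <- recs[seq_len(k)]
        aip_rows <- aip_rows[seq_len(k), , drop = FALSE]
        break
      }
    }
    if (progress && k %% 100 == 0) {
      message(sprintf("[%s] trial %d / %d", stage, k, n))
    }
  }
  new_rec <- do.call(rbind, recs)
  model$log$records <- rbind(model$log$records, new_rec)
  model$log$aip <- rbind(model$log$aip, aip_rows[seq_len(nrow(new_rec)), ,
                                                 drop = FALSE])
  model$stages_done <- union(model$stages_done, stage)
  model
}

#' Pointer to the grasp-stage novel-object probe records
#'
#' Convenience accessor: grasp-stage records split into familiar and
#' probe (novel) series with their blockwise success rates.
#'
#' @param model a trained [grasp_model()].
#' @param window block size in trials.
#' @return list(`familiar`, `novel`) of [success_rate_curve()] data.frames.
#' @export
probe_summary <- function(model, window = 50) {
  r <- model$log$records
  r <- r[r$stage == "grasp", ]
  list(familiar = success_rate_curve(r[!r$novel, ], window),
       novel = success_rate_curve(r[r$novel, ], window))
}
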