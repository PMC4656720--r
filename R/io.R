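#' Checkpoint a model to disk
#'
#' Serializes the complete model — configuration, all weights, stage and
#' epoch counters, trial log, and the saved RNG substream states — so a
#' restored run continues exactly as an uninterrupted one.  Writing is
#' atomic (temp file + rename) and repeated saves of the same state are
#' byte-identical.
#'
#' @param model a [grasp_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
checkpoint <- function(model, path) {
  stopifnot(inherits(model, "grasp_model"))
  payload <- unclass(model)
  # materialize the RNG environment so states survive serialization
  payload$rng <- list(master = model$rng$master,
                      sampling = model$rng$sampling,
                      noise = model$rng$noise,
                      init = model$rng$init)
  obj <- list(format = "affgrasp_checkpoint", version = model$version,
              payload = payload)
  tmp <- paste0(path, ".tmp")
  saveRDS(obj, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Restore a model from a checkpoint
#'
#' @param path checkpoint file written by [checkpoint()].
#' @return the restored [grasp_model()].
#' @export
restore <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path, call. = FALSE)
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("corrupt or truncated checkpoint: ", path, call. = FALSE)
  })
  if (!is.list(obj) || !identical(obj$format, "affgrasp_checkpoint")) {
    stop("not an affgrasp checkpoint: ", path, call. = FALSE)
  }
  if (!identical(obj$version, 1L)) {
    stop("checkpoint version ", obj$version,
         " not supported by this package version", call. = FALSE)
  }
  model <- obj$payload
  rng <- new.env(parent = emptyenv())
  rng$master <- model$rng$master
  rng$sampling <- model$rng$sampling
  rng$noise <- model$rng$noise
  rng$init <- model$rng$init
  class(rng) <- "ag_rng"
  model$rng <- rng
  class(model) <- "grasp_model"
  model
}

#' Export the trial log as tidy CSV
#' @param model a [grasp_model()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_trial_log <- function(model, path) {
  if (is.null(model$log$records)) stop("model has no trial log", call. = FALSE)
  utils::write.csv(model$log$records, path, row.names = FALSE)
  invisible(path)
}

#' Export a contact history as tidy CSV
#'
#' One row per contact: trial, time, body part and world coordinates.
#'
#' @param history list of `list(time, contacts)` steps
#'   (see [run_motor_phase()]).
#' @param path output CSV path.
#' @param trial trial index written to every row.
#' @return `path`, invisibly.
#' @export
export_contacts <- function(history, path, trial = 1L) {
  rows <- lapply(history, function(h) {
    if (nrow(h$contacts) == 0) return(NULL)
    cbind(trial = trial, h$contacts[, c("time", "body_part", "x", "y", "z")])
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(trial = integer(0), time = numeric(0),
                     body_part = character(0), x = numeric(0),
                     y = numeric(0), z = numeric(0))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
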