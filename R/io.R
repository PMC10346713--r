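# Dataset persistence: one directory per dataset, a manifest.json with the
# configuration echo and the trial table, and one numeric CSV per trial
# (rows = channels, columns = time samples).

#' Write / read a trial dataset directory
#'
#' \code{write_trial_dataset} persists a \code{trial_dataset} as a
#' directory: \code{manifest.json} (configuration echo plus the trial table
#' with \code{trial_id}, \code{class}, \code{section}, \code{order_index},
#' \code{fs}) and one CSV per trial.  \code{read_trial_dataset} restores
#' it.
#'
#' @param dataset A \code{trial_dataset}.
#' @param dir Dataset directory (created if needed).
#' @return \code{write_trial_dataset} returns \code{dir} invisibly;
#'   \code{read_trial_dataset} returns the \code{trial_dataset}.
#' @export
write_trial_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "trial_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  trials <- data.frame(
    trial_id = vapply(dataset$trials, `[[`, "", "trial_id"),
    class = vapply(dataset$trials, `[[`, "", "class_label"),
    section = vapply(dataset$trials, `[[`, "", "section"),
    order_index = vapply(dataset$trials, `[[`, 0L, "order_index"),
    fs = vapply(dataset$trials, `[[`, 0L, "fs"),
    stringsAsFactors = FALSE)
  cfg <- unclass(dataset$config)
  cfg$class_gain <- list(dim = dim(dataset$config$class_gain),
                         values = as.vector(dataset$config$class_gain))
  jsonlite::write_json(list(config = cfg, trials = trials),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (tr in dataset$trials)
    write.table(tr$signal, file.path(dir, paste0(tr$trial_id, ".csv")),
                sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' @rdname write_trial_dataset
#' @export
read_trial_dataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  cfg <- man$config
  class_gain <- array(cfg$class_gain$values, dim = cfg$class_gain$dim)
  config <- session_config(
    minutes_per_class = cfg$minutes_per_class,
    trial_duration_s = cfg$trial_duration_s,
    epoch_duration_s = cfg$epoch_duration_s, fs = cfg$fs,
    n_channels = cfg$n_channels, class_gain = class_gain,
    trial_gain_sd = cfg$trial_gain_sd, noise_sd = cfg$noise_sd,
    band_edges = lapply(cfg$band_edges, as.numeric), seed = cfg$seed)
  trials <- lapply(seq_len(nrow(man$trials)), function(i) {
    ti <- man$trials[i, ]
    sig <- as.matrix(read.csv(file.path(dir, paste0(ti$trial_id, ".csv")),
                              header = FALSE))
    dimnames(sig) <- NULL
    list(trial_id = ti$trial_id, class_label = ti$class,
         section = ti$section, order_index = ti$order_index,
         signal = sig, fs = ti$fs)
  })
  structure(list(trials = trials, config = config), class = "trial_dataset")
}
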