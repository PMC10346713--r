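# Trial preprocessing (decimation, zero-phase bandpass, common-average
# re-reference) and segmentation into non-overlapping epochs.

#' Preprocess a trial dataset
#'
#' Applies, in order: anti-aliased decimation to \code{target_fs}, a
#' zero-phase Butterworth bandpass (forward-backward
#' \code{\link[signal]{filtfilt}}; 2nd-order high-pass at the low edge,
#' 10th-order low-pass at the high edge), and common-average re-referencing
#' (per-time-point subtraction of the across-channel mean).  Trial and label
#' metadata are untouched.
#'
#' @param dataset A \code{trial_dataset} from [generate_session()].
#' @param target_fs Target sampling rate in Hz; must divide the current rate.
#'   Default: no decimation.
#' @param band Length-2 passband in Hz (default \code{c(0.5, 55)}); the high
#'   edge must lie below the post-decimation Nyquist frequency.  Use
#'   \code{NULL} to skip filtering.
#' @param reref Apply common-average re-referencing (default TRUE; requires
#'   more than one channel).
#' @return The preprocessed \code{trial_dataset}.
#' @export
preprocess <- function(dataset, target_fs = NULL, band = c(0.5, 55),
                       reref = TRUE) {
  stopifnot(inherits(dataset, "trial_dataset"))
  fs <- dataset$trials[[1]]$fs
  if (is.null(target_fs)) target_fs <- fs
  if (fs %% target_fs != 0)
    stopf("target_fs (%g) must divide the sampling rate (%g)", target_fs, fs)
  q <- as.integer(fs / target_fs)
  nch <- nrow(dataset$trials[[1]]$signal)
  if (reref && nch < 2)
    stopf("common-average re-referencing requires more than one channel")
  if (!is.null(band)) {
    if (length(band) != 2L || band[1] >= band[2])
      stopf("band must be c(low, high) with low < high")
    if (band[2] >= target_fs / 2)
      stopf("band high edge (%g Hz) must be below the Nyquist frequency (%g Hz)",
            band[2], target_fs / 2)
  }
  aa <- if (q > 1L)
    signal::butter(4, 0.8 * (target_fs / 2) / (fs / 2), type = "low")
  hp <- if (!is.null(band) && band[1] > 0)
    signal::butter(2, band[1] / (target_fs / 2), type = "high")
  lp <- if (!is.null(band))
    signal::butter(10, band[2] / (target_fs / 2), type = "low")

  dataset$trials <- lapply(dataset$trials, function(tr) {
    sig <- tr$signal
    out <- t(apply(sig, 1L, function(x) {
      if (q > 1L) x <- signal::filtfilt(aa, x)[seq(1L, length(x), by = q)]
      if (!is.null(hp)) x <- signal::filtfilt(hp, x)
      if (!is.null(lp)) x <- signal::filtfilt(lp, x)
      x
    }))
    if (reref) out <- sweep(out, 2L, colMeans(out), `-`)
    tr$signal <- out
    tr$fs <- as.integer(target_fs)
    tr
  })
  dataset$config$fs <- as.integer(target_fs)
  dataset
}

#' Segment trials into non-overlapping epochs
#'
#' Cuts each trial into contiguous, non-overlapping epochs of
#' \code{epoch_duration_s}; a trailing remainder shorter than one epoch is
#' discarded with a warning.
#'
#' @param dataset A \code{trial_dataset}.
#' @param epoch_duration_s Epoch length in seconds (default from the session
#'   config); must not exceed the trial duration.
#' @return An object of class \code{epoch_set}: list with \code{epochs}
#'   (each with \code{sample_id}, \code{trial_id}, \code{class_label},
#'   0-based \code{epoch_index}, \code{signal} channels x samples),
#'   \code{fs} and \code{epoch_duration_s}.
#' @export
segment_trials <- function(dataset, epoch_duration_s = NULL) {
  stopifnot(inherits(dataset, "trial_dataset"))
  if (is.null(epoch_duration_s))
    epoch_duration_s <- dataset$config$epoch_duration_s
  fs <- dataset$trials[[1]]$fs
  ep_n <- as.integer(round(fs * epoch_duration_s))
  len <- ncol(dataset$trials[[1]]$signal)
  if (ep_n > len)
    stopf("epoch (%g s) is longer than the trial (%g s)",
          epoch_duration_s, len / fs)
  n_ep <- len %/% ep_n
  if (len %% ep_n != 0)
    warnf("trial length (%g s) is not divisible by the epoch length (%g s); discarding the trailing %g s",
          len / fs, epoch_duration_s, (len %% ep_n) / fs)
  epochs <- unlist(lapply(dataset$trials, function(tr) {
    lapply(seq_len(n_ep) - 1L, function(j) {
      list(sample_id = sprintf("%s:e%02d", tr$trial_id, j),
           trial_id = tr$trial_id, class_label = tr$class_label,
           epoch_index = j,
           signal = tr$signal[, (j * ep_n + 1L):((j + 1L) * ep_n), drop = FALSE])
    })
  }), recursive = FALSE)
  structure(list(epochs = epochs, fs = fs,
                 epoch_duration_s = epoch_duration_s),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("epoch_set: %d epochs of %g s (%d channels @ %d Hz)\n",
              length(x$epochs), x$epoch_duration_s,
              nrow(x$epochs[[1]]$signal), x$fs))
  invisible(x)
}
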