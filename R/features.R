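# Per-epoch spectral features and the sample x feature table with fold-safe
# z-scoring.

# Mean periodogram over rectangular 1-s windows with 50% overlap (the plain
# Welch scheme without taper).  Returns one-sided binned power: the value at
# frequency f_j is the power (signal units^2) carried by that bin, so the
# band power is the straight sum of bins in the band.  DC and Nyquist are
# excluded.
epoch_psd <- function(sig, fs, window_s = 1, overlap = 0.5) {
  if (is.null(dim(sig))) sig <- matrix(sig, nrow = 1L)
  len <- ncol(sig)
  L <- min(as.integer(round(fs * window_s)), len)
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq(1L, len - L + 1L, by = step)
  nb <- floor((L - 1) / 2)
  freq <- seq_len(nb) * fs / L
  nch <- nrow(sig)
  acc <- matrix(0, nb, nch)
  for (s in starts) {
    X <- mvfft(t(sig[, s:(s + L - 1L), drop = FALSE]))
    acc <- acc + 2 * Mod(X[1L + seq_len(nb), , drop = FALSE])^2 / L^2
  }
  list(freq = freq, power = acc / length(starts))
}

in_band <- function(freq, band) freq >= band[1] & freq < band[2]

check_band <- function(fs, band) {
  if (length(band) != 2L || band[1] >= band[2])
    stopf("band must be c(low, high) with low < high")
  if (band[2] > fs / 2)
    stopf("band [%g, %g) Hz exceeds the Nyquist frequency %g Hz",
          band[1], band[2], fs / 2)
}

#' Band power of one channel of an epoch
#'
#' Integrates the estimated power spectrum (mean periodogram over 1-s
#' windows, 50\% overlap) over the half-open band \code{[low, high)}.  For a
#' pure sinusoid of amplitude A whose frequency falls in the band this
#' returns A^2/2; for a constant signal it returns 0.
#'
#' @param x Numeric vector: one channel of one epoch.
#' @param fs Sampling rate (Hz).
#' @param band Length-2 band edges in Hz; must lie within the Nyquist range.
#' @param window_s Periodogram window length in seconds (default 1).
#' @return Band power in signal units squared.
#' @export
band_power <- function(x, fs, band, window_s = 1) {
  check_band(fs, band)
  if (length(x) / fs < 2 / band[1])
    warnf("epoch (%g s) is shorter than 2 cycles of the band's low edge (%g Hz)",
          length(x) / fs, band[1])
  p <- epoch_psd(x, fs, window_s)
  sum(p$power[in_band(p$freq, band), 1L])
}

# DE of a band-limited Gaussian signal from its band power (natural log).
de_from_power <- function(p) 0.5 * log(2 * pi * exp(1) * p)

#' Differential entropy of one channel of an epoch
#'
#' Computes \code{0.5 * ln(2*pi*e*P)} nats, where P is the [band_power()] of
#' the epoch in \code{band} -- the differential entropy of a Gaussian signal
#' with that band power.
#'
#' @inheritParams band_power
#' @return Differential entropy in nats.
#' @export
differential_entropy <- function(x, fs, band, window_s = 1) {
  p <- band_power(x, fs, band, window_s)
  if (p <= 0) stopf("degenerate epoch: band power is zero in [%g, %g) Hz",
                    band[1], band[2])
  de_from_power(p)
}

#' Normalized spectral entropy of one channel of an epoch
#'
#' Shannon entropy of the power spectrum bins within \code{band}, normalized
#' by \code{ln(#bins)}: 1 for an exactly flat in-band spectrum, 0 when all
#' power sits in a single bin.
#'
#' @inheritParams band_power
#' @return Normalized entropy in [0, 1].
#' @export
spectral_entropy <- function(x, fs, band, window_s = 1) {
  check_band(fs, band)
  p <- epoch_psd(x, fs, window_s)
  q <- p$power[in_band(p$freq, band), 1L]
  if (length(q) < 2L)
    stopf("band [%g, %g) Hz has fewer than 2 frequency bins", band[1], band[2])
  tot <- sum(q)
  if (tot <= 0) stopf("all-zero power spectrum in band [%g, %g) Hz",
                      band[1], band[2])
  q <- q / tot
  q <- q[q > 0]
  -sum(q * log(q)) / log(length(p$freq[in_band(p$freq, band)]))
}

#' RMS and variance of one channel of an epoch
#'
#' RMS is \code{sqrt(mean(x^2))}; the variance uses the population
#' denominator n, so the identity \code{RMS^2 = variance + mean^2} holds
#' exactly.
#'
#' @param x Numeric vector.
#' @return Named numeric vector \code{c(rms, variance)}.
#' @export
rms_and_variance <- function(x) {
  m2 <- mean(x^2)
  c(rms = sqrt(m2), variance = m2 - mean(x)^2)
}

#' Build a sample x feature table from an epoch set
#'
#' Computes one of the supported per-epoch feature sets over all channels:
#' \describe{
#'   \item{bandpower}{[band_power()] in each configured band (5 x channels
#'     columns with the default bands).}
#'   \item{DE}{[differential_entropy()] in each band (5 x channels).}
#'   \item{spectral_entropy}{[spectral_entropy()] in the delta band
#'     (channels columns).}
#'   \item{rms, variance}{broadband [rms_and_variance()] (channels columns).}
#' }
#' Per-sample metadata (\code{trial_id}, \code{class_label},
#' \code{epoch_index}) is carried through so partitioners and label
#' randomizers can key on it.
#'
#' @param epochs An \code{epoch_set} from [segment_trials()].
#' @param feature_set One of \code{"bandpower"}, \code{"DE"},
#'   \code{"spectral_entropy"}, \code{"rms"}, \code{"variance"}.
#' @param band_edges Band definitions (default [default_band_edges()]).
#' @param window_s Periodogram window length in seconds.
#' @return An object of class \code{feature_table}: list with numeric matrix
#'   \code{x} (samples x features), data.frame \code{meta}, and
#'   \code{feature_set} / \code{normalization_state} tags.
#' @export
build_feature_table <- function(epochs,
                                feature_set = c("bandpower", "DE",
                                                "spectral_entropy", "rms",
                                                "variance"),
                                band_edges = default_band_edges(),
                                window_s = 1) {
  stopifnot(inherits(epochs, "epoch_set"))
  feature_set <- match.arg(feature_set)
  fs <- epochs$fs
  shapes <- vapply(epochs$epochs, function(e) dim(e$signal), integer(2))
  if (length(unique(shapes[1L, ])) != 1L || length(unique(shapes[2L, ])) != 1L)
    stopf("epochs have inconsistent channel counts or lengths")
  nch <- shapes[1L, 1L]
  ch_names <- sprintf("ch%02d", seq_len(nch))
  bands <- names(band_edges)

  row_features <- function(sig) {
    switch(feature_set,
      bandpower = ,
      DE = {
        p <- epoch_psd(sig, fs, window_s)
        out <- unlist(lapply(seq_len(nch), function(ch)
          vapply(bands, function(b)
            sum(p$power[in_band(p$freq, band_edges[[b]]), ch]), 0)))
        if (feature_set == "DE") {
          if (any(out <= 0)) stopf("degenerate epoch: zero band power")
          out <- de_from_power(out)
        }
        out
      },
      spectral_entropy = vapply(seq_len(nch), function(ch)
        spectral_entropy(sig[ch, ], fs, band_edges$delta, window_s), 0),
      rms = vapply(seq_len(nch), function(ch)
        rms_and_variance(sig[ch, ])[["rms"]], 0),
      variance = vapply(seq_len(nch), function(ch)
        rms_and_variance(sig[ch, ])[["variance"]], 0))
  }

  x <- t(vapply(epochs$epochs, function(e) row_features(e$signal),
                numeric(switch(feature_set, bandpower = , DE = length(bands) * nch,
                               nch))))
  colnames(x) <- switch(feature_set,
    bandpower = ,
    DE = as.vector(vapply(ch_names, function(ch)
      paste(feature_set, bands, ch, sep = ":"), character(length(bands)))),
    spectral_entropy = paste("spectral_entropy", "delta", ch_names, sep = ":"),
    paste(feature_set, ch_names, sep = ":"))
  meta <- data.frame(
    sample_id = vapply(epochs$epochs, `[[`, "", "sample_id"),
    trial_id = vapply(epochs$epochs, `[[`, "", "trial_id"),
    class_label = vapply(epochs$epochs, `[[`, "", "class_label"),
    epoch_index = vapply(epochs$epochs, `[[`, 0L, "epoch_index"),
    stringsAsFactors = FALSE)
  rownames(x) <- meta$sample_id
  if (anyNA(x)) stopf("feature computation produced missing values")
  new_feature_table(x, meta, feature_set)
}

new_feature_table <- function(x, meta, feature_set,
                              normalization_state = "none") {
  stopifnot(nrow(x) == nrow(meta), !anyDuplicated(colnames(x)),
            !anyDuplicated(meta$sample_id))
  structure(list(x = x, meta = meta, feature_set = feature_set,
                 normalization_state = normalization_state),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d features (%s), %d trials, normalization: %s\n",
              nrow(x$x), ncol(x$x), x$feature_set,
              length(unique(x$meta$trial_id)), x$normalization_state))
  print(table(class = x$meta$class_label))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$x)

#' @export
as.data.frame.feature_table <- function(x, ...) {
  cbind(x$meta, as.data.frame(x$x, check.names = FALSE))
}

# Row / column subsetting that keeps matrix and metadata aligned.
ft_rows <- function(table, idx) {
  new_feature_table(table$x[idx, , drop = FALSE],
                    table$meta[idx, , drop = FALSE], table$feature_set,
                    table$normalization_state)
}

ft_cols <- function(table, idx) {
  new_feature_table(table$x[, idx, drop = FALSE], table$meta,
                    table$feature_set, table$normalization_state)
}

zscore_stats <- function(x) {
  mu <- colMeans(x)
  s <- apply(x, 2L, sd)
  zero <- !is.finite(s) | s == 0
  if (any(zero)) {
    warnf("%d zero-variance feature(s); centered only, scale left at 1",
          sum(zero))
    s[zero] <- 1
  }
  list(mu = mu, s = s)
}

apply_zscore <- function(x, st) sweep(sweep(x, 2L, st$mu, `-`), 2L, st$s, `/`)

#' Fold-safe z-score normalization
#'
#' Normalizes a train/test pair of feature tables.  In mode
#' \code{"train_fitted"} the test set is scaled by the training set's column
#' means and standard deviations (no information flows from test to train);
#' in mode \code{"separate"} each table is scaled by its own statistics.
#' Zero-variance columns are centered but not scaled (with a warning).
#'
#' @param train,test \code{feature_table}s with identical feature names and
#'   disjoint sample ids.
#' @param mode \code{"train_fitted"} (default) or \code{"separate"}.
#' @return List with normalized \code{train} and \code{test} tables.
#' @export
zscore_fit_apply <- function(train, test, mode = c("train_fitted", "separate")) {
  mode <- match.arg(mode)
  stopifnot(inherits(train, "feature_table"), inherits(test, "feature_table"))
  if (!identical(colnames(train$x), colnames(test$x)))
    stopf("train and test feature names differ")
  if (length(intersect(train$meta$sample_id, test$meta$sample_id)))
    stopf("train and test share sample ids")
  st <- zscore_stats(train$x)
  train$x <- apply_zscore(train$x, st)
  test$x <- apply_zscore(test$x, if (mode == "separate")
    zscore_stats(test$x) else st)
  train$normalization_state <- mode
  test$normalization_state <- mode
  list(train = train, test = test)
}

#' Write / read a feature table as CSV with a JSON sidecar
#'
#' The CSV holds the metadata columns (\code{sample_id}, \code{trial_id},
#' \code{class_label}, \code{epoch_index}) followed by the feature columns;
#' the sidecar (same path with extension \code{.json}) records
#' \code{feature_set} and \code{normalization_state}.
#'
#' @param table A \code{feature_table}.
#' @param path CSV file path.
#' @return \code{write_feature_table} returns \code{path} invisibly;
#'   \code{read_feature_table} returns the \code{feature_table}.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  write.csv(as.data.frame(table), path, row.names = FALSE)
  side <- sub("\\.[^.]*$", ".json", path)
  jsonlite::write_json(list(feature_set = table$feature_set,
                            normalization_state = table$normalization_state),
                       side, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- c("sample_id", "trial_id", "class_label", "epoch_index")
  if (!all(meta_cols %in% names(df)))
    stopf("CSV is missing metadata columns: %s",
          paste(setdiff(meta_cols, names(df)), collapse = ", "))
  side <- sub("\\.[^.]*$", ".json", path)
  info <- if (file.exists(side)) jsonlite::read_json(side)
    else list(feature_set = "bandpower", normalization_state = "none")
  x <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  rownames(x) <- df$sample_id
  new_feature_table(x, df[, meta_cols], info$feature_set,
                    info$normalization_state)
}
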