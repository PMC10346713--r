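# Synthetic session generator: trial-structured multichannel band-limited
# signals with a per-trial multiplicative random effect (the within-trial
# correlation knob) and a per-class gain profile (the separability knob).

#' Canonical EEG frequency bands
#'
#' Delta, theta, alpha, beta and gamma band edges in Hz.  Bands are
#' half-open intervals \code{[low, high)}.
#'
#' @return Named list of length-2 numeric vectors (Hz).
#' @export
default_band_edges <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 12),
       beta = c(12, 30), gamma = c(30, 50))
}

#' Build a class-gain array with a single separability knob
#'
#' Constructs the per-class x per-band x per-channel amplitude multipliers
#' used by [session_config()].  Class 1 has unit gain everywhere; class 2's
#' gain is multiplied by \code{1 + delta} in the chosen effect bands on all
#' channels, so \code{delta} is the relative amplitude difference between
#' classes ("delta = 0" means indistinguishable classes).
#'
#' @param n_channels Number of channels.
#' @param delta Relative gain difference (>= 0) between class 2 and class 1
#'   in the effect bands.
#' @param effect_bands Character vector of band names carrying the class
#'   effect (subset of \code{names(band_edges)}).
#' @param band_edges Band definition list, see [default_band_edges()].
#' @return Numeric array of dim \code{c(2, n_bands, n_channels)}.
#' @export
make_class_gains <- function(n_channels, delta = 0.3, effect_bands = "alpha",
                             band_edges = default_band_edges()) {
  if (!is_count(n_channels) || n_channels < 1)
    stopf("n_channels must be a positive integer")
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0)
    stopf("delta must be a single non-negative number")
  bands <- names(band_edges)
  bad <- setdiff(effect_bands, bands)
  if (length(bad)) stopf("unknown effect band(s): %s", paste(bad, collapse = ", "))
  g <- array(1, dim = c(2L, length(bands), n_channels),
             dimnames = list(class = c("c1", "c2"), band = bands,
                             channel = sprintf("ch%02d", seq_len(n_channels))))
  g[2L, match(effect_bands, bands), ] <- 1 + delta
  g
}

#' Configuration of a synthetic recording session
#'
#' Describes a binary-class session split into fixed-duration trials.  Each
#' trial's multichannel signal is a sum over frequency bands of band-limited
#' unit-variance Gaussian noise, scaled by \code{class_gain[class, band,
#' channel]} and by a per-trial gain \code{g ~ Normal(1, trial_gain_sd^2)}
#' (truncated below at 0.05), plus white noise of standard deviation
#' \code{noise_sd}.  The shared per-trial gain is what makes epochs from the
#' same trial more alike than epochs from different trials of the same class.
#'
#' @param n_classes Number of classes; only binary (2) sessions are supported.
#' @param minutes_per_class Minutes of signal recorded per class (default 6).
#' @param trial_duration_s Trial length in seconds (e.g. 5, 15 or 60).
#' @param epoch_duration_s Epoch length in seconds used downstream (default 5).
#' @param fs Sampling rate in Hz (default 250).
#' @param n_channels Number of channels (default 8).
#' @param class_gain Per-class x band x channel amplitude array; defaults to
#'   [make_class_gains()] with separability \code{delta}.
#' @param delta Convenience separability knob used when \code{class_gain} is
#'   not given.
#' @param effect_bands Bands carrying the class effect (default "alpha").
#' @param trial_gain_sd Standard deviation of the per-trial multiplicative
#'   gain (the within-trial correlation knob; 0 gives i.i.d. epochs).
#' @param noise_sd Standard deviation of the additive white noise (> 0).
#' @param band_edges Band definitions, see [default_band_edges()].
#' @param seed Master seed; two independent sub-streams (session plan, signal
#'   noise) are derived from it.
#' @return An object of class \code{session_config}.
#' @export
session_config <- function(n_classes = 2L, minutes_per_class = 6,
                           trial_duration_s = 60, epoch_duration_s = 5,
                           fs = 250, n_channels = 8L, class_gain = NULL,
                           delta = 0.3, effect_bands = "alpha",
                           trial_gain_sd = 0.3, noise_sd = 1,
                           band_edges = default_band_edges(), seed = 1L) {
  if (!identical(as.integer(n_classes), 2L))
    stopf("only binary sessions are supported (n_classes = 2)")
  if (minutes_per_class <= 0 || trial_duration_s <= 0 || epoch_duration_s <= 0)
    stopf("minutes_per_class, trial_duration_s and epoch_duration_s must be positive")
  if (!is_count(fs) || fs <= 0) stopf("fs must be a positive integer (Hz)")
  if (!is_count(n_channels) || n_channels < 1)
    stopf("n_channels must be a positive integer")
  if (!is.numeric(trial_gain_sd) || trial_gain_sd < 0)
    stopf("trial_gain_sd must be >= 0")
  if (!is.numeric(noise_sd) || noise_sd <= 0) stopf("noise_sd must be > 0")
  for (b in names(band_edges)) {
    be <- band_edges[[b]]
    if (length(be) != 2L || be[1] >= be[2])
      stopf("degenerate band '%s': low edge must be below high edge", b)
    if (be[2] > fs / 2)
      stopf("band '%s' exceeds the Nyquist frequency %g Hz", b, fs / 2)
  }
  if (is.null(class_gain))
    class_gain <- make_class_gains(n_channels, delta = delta,
                                   effect_bands = effect_bands,
                                   band_edges = band_edges)
  if (!identical(dim(class_gain), c(2L, length(band_edges), as.integer(n_channels))))
    stopf("class_gain must have dim c(2, %d, %d)", length(band_edges), n_channels)
  if (any(class_gain < 0)) stopf("class_gain entries must be >= 0")
  structure(list(n_classes = 2L, minutes_per_class = minutes_per_class,
                 trial_duration_s = trial_duration_s,
                 epoch_duration_s = epoch_duration_s, fs = as.integer(fs),
                 n_channels = as.integer(n_channels), class_gain = class_gain,
                 trial_gain_sd = trial_gain_sd, noise_sd = noise_sd,
                 band_edges = band_edges, seed = as.integer(seed)),
            class = "session_config")
}

#' @export
print.session_config <- function(x, ...) {
  cat(sprintf("session_config: 2 classes, %g min/class, %g s trials, fs %d Hz, %d channels\n",
              x$minutes_per_class, x$trial_duration_s, x$fs, x$n_channels))
  cat(sprintf("  trial_gain_sd (tau) = %g, noise_sd (sigma) = %g, seed = %d\n",
              x$trial_gain_sd, x$noise_sd, x$seed))
  invisible(x)
}

trials_per_class <- function(config) {
  total_s <- config$minutes_per_class * 60
  if (abs(total_s %% config$trial_duration_s) > 1e-9)
    stopf(paste0("minutes_per_class (%g min = %g s) is not divisible by ",
                 "trial_duration_s (%g s)"),
          config$minutes_per_class, total_s, config$trial_duration_s)
  as.integer(round(total_s / config$trial_duration_s))
}

#' Plan a session: trial slots, classes and presentation order
#'
#' Computes the trial count per class from the session duration and lays the
#' trials of the two classes out in a uniformly random interleaved order
#' under the plan seed.  The plan seed stream is independent of the signal
#' noise stream, so the same plan can be re-generated with different noise.
#'
#' @param config A [session_config()].
#' @param seed Plan seed; defaults to the first sub-seed derived from
#'   \code{config$seed}.
#' @return A data.frame with columns \code{trial_id}, \code{class_label},
#'   \code{section}, \code{order_index}.
#' @export
plan_session <- function(config, seed = NULL) {
  stopifnot(inherits(config, "session_config"))
  tpc <- trials_per_class(config)
  if (is.null(seed)) seed <- derive_seeds(config$seed, 2L)[1L]
  n <- 2L * tpc
  labels <- with_seed(seed, sample(rep(c("c1", "c2"), each = tpc)))
  data.frame(trial_id = sprintf("trial%03d", seq_len(n)),
             class_label = labels,
             section = sprintf("T%g", config$trial_duration_s),
             order_index = seq_len(n),
             stringsAsFactors = FALSE)
}

# DFT bin bookkeeping for a half-open band [low, high): positive-frequency
# bin indices (1-based R indices into the DFT vector, excluding DC/Nyquist).
band_bins <- function(n, fs, band) {
  j <- seq_len(floor((n - 1) / 2))          # positive frequencies only
  f <- j * fs / n
  j[f >= band[1] & f < band[2]] + 1L        # +1: R index of DFT bin j
}

# Gaussian noise exactly confined to `band`, unit variance in expectation.
# Columns are independent channels.
band_limited_noise <- function(n, n_cols, fs, band) {
  keep <- band_bins(n, fs, band)
  if (!length(keep))
    stopf("band [%g, %g) Hz contains no DFT bins at n = %d, fs = %d",
          band[1], band[2], n, fs)
  x <- matrix(rnorm(n * n_cols), n, n_cols)
  X <- mvfft(x)
  mask <- numeric(n)
  mask[keep] <- 1
  mask[n + 2L - keep] <- 1                   # conjugate bins
  y <- Re(mvfft(X * mask, inverse = TRUE)) / n
  y * sqrt(n / (2 * length(keep)))
}

#' Generate a synthetic session
#'
#' Realizes the generative model described in [session_config()]: for each
#' trial a single gain \code{g = max(Normal(1, trial_gain_sd^2), 0.05)} is
#' drawn and shared by the whole trial; every channel is a gain-weighted sum
#' of band-limited unit-variance noise over the configured bands plus white
#' noise.  The band noise is realized in independent epoch-length blocks, so
#' the shared gain is the \emph{only} source of dependence between epochs of
#' a trial: at \code{trial_gain_sd = 0} epochs are exactly i.i.d., and each
#' epoch's in-band power follows the closed-form gamma model used by
#' [bayes_rate_oracle()].  Bit-identical output for identical seeds.
#'
#' @param config A [session_config()].
#' @param seed Master seed; defaults to \code{config$seed}.
#' @return An object of class \code{trial_dataset}: list with \code{trials}
#'   (list of trial records, each with \code{trial_id}, \code{class_label},
#'   \code{section}, \code{order_index}, \code{signal} (channels x time),
#'   \code{fs}, \code{trial_gain}) and \code{config}.
#' @export
generate_session <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "session_config"))
  seeds <- derive_seeds(seed, 2L)
  plan <- plan_session(config, seed = seeds[1L])
  n_t <- nrow(plan)
  nch <- config$n_channels
  n <- as.integer(round(config$fs * config$trial_duration_s))
  seg <- min(as.integer(round(config$fs * config$epoch_duration_s)), n)
  n_seg <- ceiling(n / seg)
  bands <- names(config$band_edges)
  trials <- with_seed(seeds[2L], {
    lapply(seq_len(n_t), function(i) {
      cls <- match(plan$class_label[i], c("c1", "c2"))
      g <- max(rnorm(1, 1, config$trial_gain_sd), 0.05)
      sig <- matrix(0, n, nch)
      for (b in seq_along(bands)) {
        bn <- do.call(rbind, lapply(seq_len(n_seg), function(s)
          band_limited_noise(seg, nch, config$fs, config$band_edges[[b]])))
        bn <- bn[seq_len(n), , drop = FALSE]
        sig <- sig + sweep(bn, 2L, config$class_gain[cls, b, ] * g, `*`)
      }
      sig <- sig + config$noise_sd * matrix(rnorm(n * nch), n, nch)
      list(trial_id = plan$trial_id[i], class_label = plan$class_label[i],
           section = plan$section[i], order_index = plan$order_index[i],
           signal = t(sig), fs = config$fs, trial_gain = g)
    })
  })
  structure(list(trials = trials, config = config), class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  n <- length(x$trials)
  cls <- vapply(x$trials, `[[`, "", "class_label")
  d <- dim(x$trials[[1]]$signal)
  cat(sprintf("trial_dataset: %d trials (%s), signal %d channels x %d samples @ %d Hz\n",
              n, paste(sprintf("%s: %d", names(table(cls)), table(cls)),
                       collapse = ", "),
              d[1], d[2], x$trials[[1]]$fs))
  invisible(x)
}

# Exact in-band power of one channel (one-sided, DC excluded), via the DFT.
inband_power <- function(x, fs, band) {
  n <- length(x)
  keep <- band_bins(n, fs, band)
  X <- fft(x)
  sum(2 * Mod(X[keep])^2 / n^2)
}

#' Monte-Carlo estimate of the best achievable single-epoch accuracy
#'
#' Estimates the accuracy of the generator-optimal (Bayes) classifier on
#' independent single-epoch samples from a [session_config()].  Under the
#' generative model the vector of in-band powers is sufficient: given the
#' trial gain \code{g}, the power of band \code{b} on channel \code{ch} is
#' \code{(gain^2 g^2 + noise_sd^2 * 2 k_b / N) * Gamma(k_b)/k_b}, with
#' \code{k_b} DFT bins in the band.  The classifier evaluates the exact
#' likelihood ratio, integrating over \code{g} by quantile quadrature of the
#' truncated Normal prior.  Samples are drawn directly in the spectral
#' domain from the same distribution the time-domain generator induces.
#'
#' @param config A [session_config()]; the epoch is one
#'   \code{epoch_duration_s} at \code{fs}.
#' @param n_mc Number of Monte-Carlo samples (>= 1000).
#' @param seed RNG seed.
#' @param g_grid Number of quadrature points for the trial-gain integral.
#' @return Object of class \code{bayes_rate}: list with \code{accuracy},
#'   \code{se} (binomial standard error) and \code{n_mc}.
#' @export
bayes_rate_oracle <- function(config, n_mc = 10000L, seed = 1L, g_grid = 61L) {
  stopifnot(inherits(config, "session_config"))
  if (!is_count(n_mc) || n_mc < 1000) stopf("n_mc must be an integer >= 1000")
  n <- as.integer(round(config$fs * config$epoch_duration_s))
  bands <- names(config$band_edges)
  nch <- config$n_channels
  k_b <- vapply(config$band_edges, function(be) length(band_bins(n, config$fs, be)), 0L)
  if (any(k_b == 0)) stopf("some band has no DFT bins at this epoch length")
  # feature layout: band varies fastest, then channel
  feat_k <- rep(k_b, times = nch)
  noise_pow <- config$noise_sd^2 * 2 * feat_k / n
  gain2 <- function(cls)                    # squared gains, same layout
    as.vector(config$class_gain[cls, , ])^2
  tau <- config$trial_gain_sd
  gq <- pmax(qnorm((seq_len(g_grid) - 0.5) / g_grid, 1, tau), 0.05)
  if (tau == 0) gq <- 1
  nf <- length(feat_k)

  res <- with_seed(seed, {
    y <- rep(1:2, length.out = n_mc)
    g <- pmax(rnorm(n_mc, 1, tau), 0.05)
    P <- matrix(0, n_mc, nf)
    for (cls in 1:2) {
      idx <- which(y == cls)
      v <- outer(g[idx]^2, gain2(cls)) + rep(noise_pow, each = length(idx))
      P[idx, ] <- v * matrix(rgamma(length(idx) * nf, shape = feat_k),
                             length(idx), nf, byrow = TRUE) /
        rep(feat_k, each = length(idx))
    }
    list(y = y, P = P)
  })

  # Log-likelihood per class: sum_f Gamma(k_f, rate = k_f / v) log-density,
  # dropping terms constant across classes/grid points; reduces to one
  # matrix product P %*% rates.
  ll_class <- function(cls) {
    rates <- vapply(gq, function(g) feat_k / (gain2(cls) * g^2 + noise_pow),
                    numeric(nf))                       # nf x G
    const <- colSums(feat_k * log(rates))              # G
    lin <- -res$P %*% rates                            # n_mc x G
    lin <- sweep(lin, 2L, const, `+`)
    m <- apply(lin, 1L, max)
    m + log(rowMeans(exp(lin - m)))
  }
  pred <- ifelse(ll_class(2L) > ll_class(1L), 2L, 1L)
  acc <- mean(pred == res$y)
  structure(list(accuracy = acc, se = sqrt(acc * (1 - acc) / n_mc),
                 n_mc = as.integer(n_mc)),
            class = "bayes_rate")
}

#' @export
print.bayes_rate <- function(x, ...) {
  cat(sprintf("Bayes-rate oracle: accuracy %.4f (SE %.4f, n_mc = %d)\n",
              x$accuracy, x$se, x$n_mc))
  invisible(x)
}
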