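# Shared fixtures, built in code.

# A feature table built directly (no signal generation): per-class mean shift
# `delta` on `effect_features`, a per-trial random intercept `trial_sd` shared
# by all epochs of a trial (the correlation surrogate), unit noise elsewhere.
make_toy_table <- function(n_trials_per_class = 6, epochs_per_trial = 4,
                           n_features = 5, delta = 0, trial_sd = 0,
                           effect_features = 1, seed = 1) {
  set.seed(seed)
  classes <- rep(c("c1", "c2"), each = n_trials_per_class)
  trial_ids <- sprintf("t%02d", seq_along(classes))
  rows <- do.call(rbind, lapply(seq_along(trial_ids), function(i) {
    u <- rnorm(1, 0, trial_sd)
    m <- matrix(rnorm(epochs_per_trial * n_features), epochs_per_trial)
    m <- m + u
    if (classes[i] == "c2")
      m[, effect_features] <- m[, effect_features] + delta
    m
  }))
  colnames(rows) <- sprintf("f%02d", seq_len(n_features))
  meta <- data.frame(
    sample_id = sprintf("%s:e%02d", rep(trial_ids, each = epochs_per_trial),
                        rep(seq_len(epochs_per_trial) - 1L,
                            length(trial_ids))),
    trial_id = rep(trial_ids, each = epochs_per_trial),
    class_label = rep(classes, each = epochs_per_trial),
    epoch_index = rep(seq_len(epochs_per_trial) - 1L, length(trial_ids)),
    stringsAsFactors = FALSE)
  rownames(rows) <- meta$sample_id
  trialcv:::new_feature_table(rows, meta, "toy")
}

# An epoch_set of white-noise epochs, for feature-dimension checks.
make_noise_epochs <- function(n_epochs = 2, n_channels = 4, fs = 128,
                              epoch_s = 1, seed = 1) {
  set.seed(seed)
  eps <- lapply(seq_len(n_epochs), function(i)
    list(sample_id = sprintf("t%02d:e00", i), trial_id = sprintf("t%02d", i),
         class_label = c("c1", "c2")[1 + i %% 2], epoch_index = 0L,
         signal = matrix(rnorm(n_channels * fs * epoch_s), n_channels)))
  structure(list(epochs = eps, fs = fs, epoch_duration_s = epoch_s),
            class = "epoch_set")
}

# Small generated session reused by several feature tests.
small_session <- function(seed = 11, ...) {
  generate_session(session_config(n_channels = 2, fs = 128,
                                  trial_duration_s = 15,
                                  minutes_per_class = 1, delta = 0.2,
                                  trial_gain_sd = 0.3, seed = seed, ...))
}
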