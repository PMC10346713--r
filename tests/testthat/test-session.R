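# Synthetic session generator: planning arithmetic, generative contract,
# correlation structure, Bayes-rate oracle.

test_that("planner reproduces the session design trial counts", {
  for (case in list(c(6, 5, 72), c(6, 15, 24), c(6, 60, 6), c(1, 60, 1))) {
    cfg <- session_config(minutes_per_class = case[1],
                          trial_duration_s = case[2], n_channels = 2,
                          fs = 128)
    plan <- plan_session(cfg)
    expect_equal(sum(plan$class_label == "c1"), case[3])
    expect_equal(sum(plan$class_label == "c2"), case[3])
  }
})

test_that("planner counts match closed-form arithmetic for random valid configs", {
  set.seed(42)
  for (i in 1:25) {
    tpc <- sample(1:40, 1)
    dur <- sample(c(2, 5, 10, 30, 60), 1)
    cfg <- session_config(minutes_per_class = tpc * dur / 60,
                          trial_duration_s = dur, n_channels = 2, fs = 128)
    plan <- plan_session(cfg, seed = i)
    expect_equal(nrow(plan), 2 * tpc)
    expect_equal(unname(table(plan$class_label)), c(tpc, tpc),
                 ignore_attr = TRUE)
    expect_equal(plan$order_index, seq_len(2 * tpc))
  }
})

test_that("non-divisible session durations raise an error naming the fields", {
  cfg <- session_config(minutes_per_class = 6, trial_duration_s = 7,
                        n_channels = 2, fs = 128)
  expect_error(plan_session(cfg), "minutes_per_class.*trial_duration_s")
})

test_that("class order is randomized under the plan seed and reproducible", {
  cfg <- session_config(minutes_per_class = 3, trial_duration_s = 5,
                        n_channels = 2, fs = 128)
  p1 <- plan_session(cfg, seed = 1)
  p2 <- plan_session(cfg, seed = 1)
  p3 <- plan_session(cfg, seed = 2)
  expect_identical(p1, p2)
  expect_false(identical(p1$class_label, p3$class_label))
  # interleaved, not blocked: both classes appear in each half
  half <- seq_len(nrow(p1) / 2)
  expect_gt(length(unique(p1$class_label[half])), 1)
})

test_that("generated sessions have the declared shape and are seed-deterministic", {
  cfg <- session_config(minutes_per_class = 6, trial_duration_s = 60,
                        fs = 250, n_channels = 4, seed = 9)
  ds <- generate_session(cfg)
  expect_length(ds$trials, 12)
  expect_true(all(vapply(ds$trials, function(tr)
    identical(dim(tr$signal), c(4L, 15000L)), TRUE)))
  expect_false(anyDuplicated(vapply(ds$trials, `[[`, "", "trial_id")) > 0)
  ds2 <- generate_session(cfg)
  expect_identical(ds, ds2)
  ds3 <- generate_session(cfg, seed = 10)
  expect_false(identical(ds$trials[[1]]$signal, ds3$trials[[1]]$signal))
})

test_that("invalid configurations are rejected", {
  expect_error(session_config(trial_gain_sd = -0.1, n_channels = 2),
               "trial_gain_sd")
  expect_error(session_config(noise_sd = 0, n_channels = 2), "noise_sd")
  expect_error(session_config(n_channels = 2, fs = 128,
                              band_edges = list(alpha = c(12, 8))),
               "degenerate band")
  expect_error(session_config(n_channels = 2, fs = 64,
                              band_edges = list(gamma = c(30, 50))),
               "Nyquist")
  expect_error(session_config(n_classes = 3, n_channels = 2), "binary")
})

test_that("band-limited noise is exactly confined and unit-variance in expectation", {
  set.seed(3)
  bn <- trialcv:::band_limited_noise(640, 50, 128, c(8, 12))
  pin <- apply(bn, 2, trialcv:::inband_power, fs = 128, band = c(8, 12))
  pout <- apply(bn, 2, trialcv:::inband_power, fs = 128, band = c(20, 40))
  expect_lt(max(pout), 1e-20)
  expect_equal(mean(pin), 1, tolerance = 0.1)
})

test_that("trial gains are truncated below at 0.05", {
  cfg <- session_config(minutes_per_class = 2, trial_duration_s = 5,
                        n_channels = 1, fs = 128, trial_gain_sd = 3,
                        seed = 4)
  g <- vapply(generate_session(cfg)$trials, `[[`, 0, "trial_gain")
  expect_true(all(g >= 0.05))
  expect_true(any(g == 0.05))   # heavy-tailed tau makes truncation certain here
})

test_that("in-band epoch powers follow the analytic gamma model", {
  # mean in-band power of the signal = gain^2 E[g^2] + sigma^2 * 2k/N
  cfg <- session_config(minutes_per_class = 5, trial_duration_s = 5,
                        n_channels = 1, fs = 128, delta = 0,
                        trial_gain_sd = 0.3, noise_sd = 1, seed = 5)
  ds <- generate_session(cfg)
  p <- vapply(ds$trials, function(tr)
    trialcv:::inband_power(tr$signal[1, ], 128, c(8, 12)), 0)
  k <- length(trialcv:::band_bins(640, 128, c(8, 12)))
  expected <- 1 * (1 + 0.3^2) + 1 * 2 * k / 640
  expect_equal(mean(p), expected, tolerance = 0.1)
})

test_that("epochs of one trial are more correlated than epochs of different trials iff tau > 0", {
  wi <- bw <- matrix(NA_real_, 20, 2)
  for (r in 1:20) {
    for (ti in 1:2) {
      tau <- c(0, 0.4)[ti]
      cfg <- session_config(n_channels = 2, fs = 128, trial_duration_s = 60,
                            minutes_per_class = 3, delta = 0,
                            trial_gain_sd = tau, seed = 1000 + 31 * r + ti)
      ft <- build_feature_table(segment_trials(generate_session(cfg)),
                                "bandpower")
      f <- scale(ft$x[, "bandpower:alpha:ch01"])[, 1]
      tr <- ft$meta$trial_id
      cm <- tcrossprod(f) * length(f) / (length(f) - 1)
      same_tr <- outer(tr, tr, "==") & !diag(length(f))
      diff_tr <- outer(ft$meta$class_label, ft$meta$class_label, "==") &
        !outer(tr, tr, "==")
      wi[r, ti] <- mean(cm[same_tr])
      bw[r, ti] <- mean(cm[diff_tr])
    }
  }
  d0 <- wi[, 1] - bw[, 1]      # tau = 0: indistinguishable
  d1 <- wi[, 2] - bw[, 2]      # tau > 0: clearly larger within trial
  expect_lt(abs(mean(d0)) / (sd(d0) / sqrt(20)), 3)
  expect_gt(mean(d1) / (sd(d1) / sqrt(20)), 5)
})

test_that("trial statistics are unrelated to presentation order", {
  ord <- pow <- c()
  for (r in 1:30) {
    cfg <- session_config(n_channels = 1, fs = 128, trial_duration_s = 5,
                          minutes_per_class = 1, delta = 0,
                          trial_gain_sd = 0.3, seed = 2000 + r)
    ds <- generate_session(cfg)
    pow <- c(pow, vapply(ds$trials, function(tr) mean(tr$signal^2), 0))
    ord <- c(ord, vapply(ds$trials, `[[`, 0L, "order_index"))
  }
  expect_lt(abs(cor(ord, pow)), 3 / sqrt(length(ord)))
})

test_that("bayes oracle hits chance at delta = 0 and the ceiling at large delta", {
  o0 <- bayes_rate_oracle(session_config(n_channels = 2, fs = 128,
                                         delta = 0, seed = 1),
                          n_mc = 10000, seed = 1)
  expect_lt(abs(o0$accuracy - 0.5), 3 * o0$se)
  oh <- bayes_rate_oracle(session_config(n_channels = 2, fs = 128,
                                         delta = 5, noise_sd = 0.05,
                                         trial_gain_sd = 0, seed = 1),
                          n_mc = 10000, seed = 1)
  expect_gt(oh$accuracy, 0.99)
  expect_error(bayes_rate_oracle(session_config(n_channels = 2, fs = 128),
                                 n_mc = 100), "n_mc")
})

test_that("bayes oracle reproduces the frozen mid-separability reference", {
  # frozen regression value: delta 0.1, tau 0.3, 2 channels, 128 Hz,
  # n_mc = 1e5, seed 42
  o <- bayes_rate_oracle(session_config(n_channels = 2, fs = 128,
                                        delta = 0.1, trial_gain_sd = 0.3,
                                        seed = 1),
                         n_mc = 100000, seed = 42)
  expect_equal(o$accuracy, 0.69651, tolerance = 0.008)
})

test_that("dataset directories round-trip through manifest + per-trial CSVs", {
  dir <- withr::local_tempdir()
  cfg <- session_config(minutes_per_class = 0.5, trial_duration_s = 5,
                        n_channels = 2, fs = 128, seed = 6)
  ds <- generate_session(cfg)
  write_trial_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_trial_dataset(dir)
  expect_equal(length(back$trials), length(ds$trials))
  for (i in seq_along(ds$trials)) {
    expect_identical(back$trials[[i]]$class_label, ds$trials[[i]]$class_label)
    expect_equal(back$trials[[i]]$signal, ds$trials[[i]]$signal,
                 tolerance = 1e-12)
  }
})
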