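# CV engine: partitioners, label randomization, repeated-run CV contract.

test_that("stratified k-fold partitions the T5-style design into balanced sets", {
  tab <- make_toy_table(n_trials_per_class = 72, epochs_per_trial = 1,
                        n_features = 2, seed = 1)
  sets <- kfold_partition(tab, 6, seed = 1)
  expect_length(sets, 6)
  expect_true(all(lengths(sets) == 24))
  cls <- function(ids) table(tab$meta$class_label[match(ids,
                                                        tab$meta$sample_id)])
  for (s in sets) expect_equal(unname(cls(s)), c(12, 12), ignore_attr = TRUE)
})

test_that("partitions are disjoint with full coverage across random configs", {
  set.seed(2)
  for (i in 1:60) {
    k <- sample(2:6, 1)
    tpc <- k * sample(1:5, 1)
    tab <- make_toy_table(n_trials_per_class = tpc, epochs_per_trial = 1,
                          n_features = 2, seed = i)
    sets <- kfold_partition(tab, k, stratified = sample(c(TRUE, FALSE), 1),
                            seed = i)
    all_ids <- unlist(sets)
    expect_false(anyDuplicated(all_ids) > 0)
    expect_setequal(all_ids, tab$meta$sample_id)
  }
})

test_that("partitions are seed-deterministic and collision-free across seeds", {
  tab <- make_toy_table(n_trials_per_class = 24, epochs_per_trial = 1,
                        n_features = 2, seed = 3)
  expect_identical(kfold_partition(tab, 6, seed = 5),
                   kfold_partition(tab, 6, seed = 5))
  keys <- vapply(1:100, function(s)
    paste(unlist(kfold_partition(tab, 6, seed = s)), collapse = ","), "")
  expect_equal(length(unique(keys)), 100)
})

test_that("non-divisible fold sizes are a hard error naming counts", {
  tab <- make_toy_table(n_trials_per_class = 7, epochs_per_trial = 1,
                        n_features = 2)
  expect_error(kfold_partition(tab, 6, seed = 1), "7 samples")
  expect_error(blockwise_partition(tab, 6, seed = 1), "7 trials")
})

test_that("block-wise partitions never split a trial across sets", {
  tab <- make_toy_table(n_trials_per_class = 6, epochs_per_trial = 12,
                        n_features = 2, seed = 4)
  sets <- blockwise_partition(tab, 6, seed = 2)
  expect_true(all(lengths(sets) == 24))          # 1 trial per class per set
  trial_of <- function(ids) unique(tab$meta$trial_id[match(ids,
                                                           tab$meta$sample_id)])
  trials_by_set <- lapply(sets, trial_of)
  expect_true(all(lengths(trials_by_set) == 2))
  expect_false(anyDuplicated(unlist(trials_by_set)) > 0)
  # exclusivity under many random configs
  set.seed(5)
  for (i in 1:30) {
    b <- sample(2:4, 1)
    tab_i <- make_toy_table(n_trials_per_class = b * sample(1:3, 1),
                            epochs_per_trial = sample(2:5, 1),
                            n_features = 2, seed = 100 + i)
    sets_i <- blockwise_partition(tab_i, b, seed = i)
    tr <- lapply(sets_i, function(ids)
      unique(tab_i$meta$trial_id[match(ids, tab_i$meta$sample_id)]))
    expect_false(anyDuplicated(unlist(tr)) > 0)
    expect_setequal(unlist(sets_i), tab_i$meta$sample_id)
  }
})

test_that("with one epoch per trial the two partitioners induce the same distribution", {
  tab <- make_toy_table(n_trials_per_class = 6, epochs_per_trial = 1,
                        n_features = 2, seed = 6)
  n <- nrow(tab$x)
  co_freq <- function(partitioner) {
    acc <- matrix(0, n, n)
    for (s in 1:1000) {
      sets <- partitioner(tab, 3, TRUE, s)
      for (ids in sets) {
        idx <- match(ids, tab$meta$sample_id)
        acc[idx, idx] <- acc[idx, idx] + 1
      }
    }
    acc / 1000
  }
  f_k <- co_freq(kfold_partition)
  f_b <- co_freq(blockwise_partition)
  off <- upper.tri(f_k)
  expect_lt(max(abs(f_k[off] - f_b[off])), 0.07)  # ~3 binomial SEs
})

test_that("trial-level randomization flips exactly half the trials per class", {
  tab <- make_toy_table(n_trials_per_class = 4, epochs_per_trial = 3,
                        n_features = 2, seed = 7)
  out <- randomize_labels(tab, label_randomization("trial", seed = 3))
  expect_equal(table(out$meta$class_label), table(tab$meta$class_label))
  per_trial <- unique(out$meta[c("trial_id", "class_label", "class_orig")])
  expect_equal(nrow(per_trial), 8)               # labels constant within trial
  flips <- per_trial$class_label != per_trial$class_orig
  expect_equal(unname(tapply(flips, per_trial$class_orig, sum)), c(2, 2),
               ignore_attr = TRUE)
})

test_that("level none is the identity and odd counts are rejected", {
  tab <- make_toy_table(n_trials_per_class = 4, epochs_per_trial = 3)
  expect_identical(randomize_labels(tab, label_randomization("none")), tab)
  tab_odd <- make_toy_table(n_trials_per_class = 3, epochs_per_trial = 3)
  expect_error(randomize_labels(tab_odd, label_randomization("trial")),
               "odd trial count")
  tab_odd_s <- make_toy_table(n_trials_per_class = 3, epochs_per_trial = 3)
  expect_error(randomize_labels(tab_odd_s, label_randomization("sample")),
               "odd")
})

test_that("sample-level randomization mixes labels within trials at rate one half", {
  tab <- make_toy_table(n_trials_per_class = 6, epochs_per_trial = 12,
                        n_features = 2, seed = 8)
  # per-class flip totals are exact, so look at one trial's flip fraction,
  # which is hypergeometric with mean one half
  fracs <- vapply(1:200, function(s) {
    out <- randomize_labels(tab, label_randomization("sample"), seed = s)
    flipped <- out$meta$class_label != out$meta$class_orig
    mean(flipped[out$meta$trial_id == "t01"])
  }, 0)
  expect_equal(table(randomize_labels(tab, label_randomization("sample"),
                                      seed = 1)$meta$class_label),
               table(tab$meta$class_label))
  expect_lt(abs(mean(fracs) - 0.5), 3 * sd(fracs) / sqrt(200))
})

test_that("run_cv aggregates runs x folds and replays exactly from its seed", {
  tab <- make_toy_table(n_trials_per_class = 6, epochs_per_trial = 2,
                        n_features = 4, delta = 0.5, seed = 9)
  res <- run_cv(tab, cv_scheme("sample_kfold", k = 6, runs = 5, seed = 11),
                sel_m = 4)
  expect_equal(dim(res$accuracies), c(5, 6))
  expect_equal(res$mean_accuracy, mean(res$accuracies))
  expect_true(all(res$n_test_per_fold == 4))
  res2 <- run_cv(tab, cv_scheme("sample_kfold", k = 6, runs = 5, seed = 11),
                 sel_m = 4)
  expect_identical(res$accuracies, res2$accuracies)
  res3 <- run_cv(tab, cv_scheme("sample_kfold", k = 6, runs = 5, seed = 12),
                 sel_m = 4)
  expect_false(identical(res$accuracies, res3$accuracies))
  # every sample appears in exactly one test fold per run
  for (r in 1:5)
    expect_setequal(unlist(res$folds[[r]]), tab$meta$sample_id)
})

test_that("a trivially separable table scores 100 percent", {
  tab <- make_toy_table(n_trials_per_class = 6, epochs_per_trial = 2,
                        n_features = 3, delta = 40, seed = 10)
  for (mode in c("sample_kfold", "trial_blockwise")) {
    res <- run_cv(tab, cv_scheme(mode, k = 3, runs = 2, seed = 1), sel_m = 3)
    expect_equal(res$mean_accuracy, 100)
  }
})

test_that("run_cv refuses pre-normalized tables", {
  tab <- make_toy_table(n_trials_per_class = 6, epochs_per_trial = 2)
  tab$normalization_state <- "train_fitted"
  expect_error(run_cv(tab, cv_scheme("sample_kfold", k = 3, runs = 1)),
               "unnormalized")
})

test_that("both normalization variants run and differ only through scaling", {
  tab <- make_toy_table(n_trials_per_class = 6, epochs_per_trial = 2,
                        n_features = 4, delta = 1, seed = 12)
  a <- run_cv(tab, cv_scheme("sample_kfold", k = 3, runs = 2, seed = 4),
              sel_m = 4, norm_mode = "train_fitted")
  b <- run_cv(tab, cv_scheme("sample_kfold", k = 3, runs = 2, seed = 4),
              sel_m = 4, norm_mode = "separate")
  expect_identical(a$folds, b$folds)            # same partitions, same seeds
  expect_true(is.finite(b$mean_accuracy))
})

test_that("k-fold inflates and block-wise does not on correlated trial-randomized data", {
  # one-dataset version of the central asymmetry (the full replicated
  # property lives with the acceptance checks)
  kf <- bl <- c()
  for (r in 1:3) {
    cfg <- session_config(n_channels = 4, fs = 128, trial_duration_s = 60,
                          minutes_per_class = 6, delta = 0.05,
                          trial_gain_sd = 0.5, seed = 3000 + r)
    ft <- build_feature_table(segment_trials(generate_session(cfg)),
                              "bandpower")
    kf[r] <- run_cv(ft, cv_scheme("sample_kfold", 6, runs = 2, seed = r),
                    rand = label_randomization("trial"), sel_m = 20,
                    clf = classifier_spec("knn"))$mean_accuracy
    bl[r] <- run_cv(ft, cv_scheme("trial_blockwise", 6, runs = 2, seed = r),
                    rand = label_randomization("trial"), sel_m = 20,
                    clf = classifier_spec("knn"))$mean_accuracy
  }
  expect_gt(mean(kf), mean(bl) + 10)
})

test_that("serialized cv results carry the full grid and flat CSV", {
  dir <- withr::local_tempdir()
  tab <- make_toy_table(n_trials_per_class = 6, epochs_per_trial = 2,
                        n_features = 3, delta = 1, seed = 13)
  res <- run_cv(tab, cv_scheme("sample_kfold", k = 3, runs = 2, seed = 2),
                sel_m = 3)
  write_cv_result(res, json_path = file.path(dir, "res.json"),
                  csv_path = file.path(dir, "res.csv"))
  flat <- read.csv(file.path(dir, "res.csv"))
  expect_equal(nrow(flat), 6)
  expect_equal(mean(flat$accuracy), res$mean_accuracy)
  js <- jsonlite::read_json(file.path(dir, "res.json"), simplifyVector = TRUE)
  expect_equal(js$mean_accuracy, res$mean_accuracy)
  expect_equal(NROW(js$seeds), 2)   # one seed triple per run
})
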