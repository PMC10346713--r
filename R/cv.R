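# Sample-level k-fold CV, trial-level block-wise CV, repeated runs, and the
# trial-/sample-level label-randomization diagnostics.

#' Describe a cross-validation scheme
#'
#' @param mode \code{"sample_kfold"} (random partition of samples; epochs of
#'   one trial may be split across train and test) or
#'   \code{"trial_blockwise"} (random partition of trials; all epochs of a
#'   trial stay on one side of every split).
#' @param k Number of folds/blocks (>= 2).
#' @param runs Number of repeated runs; the reported accuracy is the
#'   unweighted mean over all \code{runs x k} fold accuracies.
#' @param stratified Class-balanced partitions (default TRUE); requires the
#'   per-class sample (or trial) count to be divisible by \code{k}.
#' @param seed Master seed of the scheme; per-run randomization and
#'   partition sub-seeds are derived from it and recorded in the result.
#' @return Object of class \code{cv_scheme}.
#' @export
cv_scheme <- function(mode = c("sample_kfold", "trial_blockwise"), k = 6L,
                      runs = 5L, stratified = TRUE, seed = 1L) {
  mode <- match.arg(mode)
  if (!is_count(k) || k < 2) stopf("k must be an integer >= 2")
  if (!is_count(runs) || runs < 1) stopf("runs must be an integer >= 1")
  structure(list(mode = mode, k = as.integer(k), runs = as.integer(runs),
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "cv_scheme")
}

#' Describe a label-randomization diagnostic
#'
#' @param level \code{"none"}, \code{"trial"} (relabel half of each class's
#'   trials as the other class, keeping labels constant within trials) or
#'   \code{"sample"} (relabel half of each class's samples independently of
#'   trial structure).  Both levels preserve the overall class counts
#'   exactly.
#' @param seed Seed used when [randomize_labels()] is called directly;
#'   inside [run_cv()] a fresh sub-seed is derived for every run.
#' @return Object of class \code{label_randomization}.
#' @export
label_randomization <- function(level = c("none", "trial", "sample"),
                                seed = 1L) {
  structure(list(level = match.arg(level), seed = as.integer(seed)),
            class = "label_randomization")
}

deal <- function(ids, k) {
  n <- length(ids)
  split(ids, rep(seq_len(k), each = n / k))
}

#' Partition samples into k disjoint sets
#'
#' Random, optionally class-stratified partition of the sample ids into
#' \code{k} equal sets.  Deterministic given the seed.  Non-divisible counts
#' are a hard error (the supported designs are exactly divisible).
#'
#' @param table A \code{feature_table}.
#' @param k Number of sets.
#' @param stratified Equal per-class counts in every set (default TRUE).
#' @param seed RNG seed.
#' @return List of \code{k} character vectors of sample ids.
#' @export
kfold_partition <- function(table, k, stratified = TRUE, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  ids <- table$meta$sample_id
  with_seed(seed, {
    if (stratified) {
      by_class <- split(ids, table$meta$class_label)
      for (cl in names(by_class))
        if (length(by_class[[cl]]) %% k != 0)
          stopf("class '%s' has %d samples, not divisible by k = %d",
                cl, length(by_class[[cl]]), k)
      parts <- lapply(by_class, function(s) deal(sample(s), k))
      lapply(seq_len(k), function(i)
        unlist(lapply(parts, `[[`, i), use.names = FALSE))
    } else {
      if (length(ids) %% k != 0)
        stopf("%d samples not divisible by k = %d", length(ids), k)
      deal(sample(ids), k)
    }
  })
}

#' Partition samples into b disjoint sets grouped by trial
#'
#' Random, optionally class-stratified partition of the \emph{trials} into
#' \code{b} sets; each returned set contains all sample ids of its trials,
#' so no trial ever spans two sets.
#'
#' @param table A \code{feature_table}; every trial must carry a single
#'   class label.
#' @param b Number of sets; the per-class trial count must be divisible by
#'   \code{b}.
#' @param stratified Equal per-class trial counts in every set (default
#'   TRUE).
#' @param seed RNG seed.
#' @return List of \code{b} character vectors of sample ids.
#' @export
blockwise_partition <- function(table, b, stratified = TRUE, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  tcl <- unique(table$meta[c("trial_id", "class_label")])
  if (anyDuplicated(tcl$trial_id))
    stopf("block-wise partitioning requires a single class label per trial")
  by_trial <- split(table$meta$sample_id, table$meta$trial_id)
  with_seed(seed, {
    trial_sets <- if (stratified) {
      by_class <- split(tcl$trial_id, tcl$class_label)
      for (cl in names(by_class))
        if (length(by_class[[cl]]) %% b != 0)
          stopf("class '%s' has %d trials, not divisible by b = %d",
                cl, length(by_class[[cl]]), b)
      parts <- lapply(by_class, function(s) deal(sample(s), b))
      lapply(seq_len(b), function(i)
        unlist(lapply(parts, `[[`, i), use.names = FALSE))
    } else {
      if (nrow(tcl) %% b != 0)
        stopf("%d trials not divisible by b = %d", nrow(tcl), b)
      deal(sample(tcl$trial_id), b)
    }
    lapply(trial_sets, function(tr)
      unlist(by_trial[tr], use.names = FALSE))
  })
}

#' Randomize class labels at the trial or sample level
#'
#' Trial level: for each class in turn, half of its trials are drawn at
#' random and all their samples are relabelled as the other class -- class
#' differences are masked while within-trial label homogeneity and the
#' temporal structure stay intact.  Sample level: half of each class's
#' samples are relabelled individually, destroying the trial-aligned label
#' structure as well.  Overall class counts are preserved exactly; the
#' original labels are kept in the metadata column \code{class_orig}.
#'
#' @param table A binary-labeled \code{feature_table}.
#' @param spec A [label_randomization()].
#' @param seed Overrides \code{spec$seed} when given.
#' @return The relabelled \code{feature_table} (unchanged for level
#'   \code{"none"}).
#' @export
randomize_labels <- function(table, spec, seed = NULL) {
  stopifnot(inherits(table, "feature_table"),
            inherits(spec, "label_randomization"))
  if (spec$level == "none") return(table)
  seed <- seed %||% spec$seed
  classes <- sort(unique(table$meta$class_label))
  if (length(classes) != 2L)
    stopf("label randomization requires binary labels")
  other <- stats::setNames(rev(classes), classes)
  meta <- table$meta
  meta$class_orig <- meta$class_label
  if (spec$level == "trial") {
    tcl <- unique(meta[c("trial_id", "class_orig")])
    if (anyDuplicated(tcl$trial_id))
      stopf("trial-level randomization requires a single class label per trial")
    flip <- with_seed(seed, unlist(lapply(classes, function(cl) {
      tr <- tcl$trial_id[tcl$class_orig == cl]
      if (length(tr) %% 2L != 0)
        stopf("class '%s' has an odd trial count (%d); trial-level randomization needs even counts",
              cl, length(tr))
      sample(tr, length(tr) / 2)
    })))
    hit <- meta$trial_id %in% flip
  } else {
    flip <- with_seed(seed, unlist(lapply(classes, function(cl) {
      s <- meta$sample_id[meta$class_orig == cl]
      if (length(s) %% 2L != 0)
        stopf("class '%s' has an odd sample count (%d); sample-level randomization needs even counts",
              cl, length(s))
      sample(s, length(s) / 2)
    })))
    hit <- meta$sample_id %in% flip
  }
  meta$class_label[hit] <- other[meta$class_orig[hit]]
  table$meta <- meta
  table
}

#' Run repeated cross-validation with in-fold selection and normalization
#'
#' Executes the full procedure on an unnormalized feature table.  Each run:
#' labels are (re-)randomized with a fresh sub-seed, the samples (or trials)
#' are partitioned, and each fold is scored by z-scoring
#' ([zscore_fit_apply()]), selecting features on the training half only
#' ([mrmr_select()]) and training/evaluating the classifier
#' ([train_eval()]).  The reported accuracy is the unweighted mean over all
#' \code{runs x k} fold accuracies.  Fully reproducible from the scheme
#' seed; all derived sub-seeds and fold memberships are recorded in the
#' result.
#'
#' @param table Unnormalized \code{feature_table}.
#' @param scheme A [cv_scheme()].
#' @param rand A [label_randomization()] (default: none).
#' @param sel_m mRMR target dimensionality (default 30).
#' @param clf A [classifier_spec()] (default: LDA).
#' @param norm_mode Per-fold normalization mode, see [zscore_fit_apply()].
#' @return Object of class \code{cv_result}: per-run-per-fold accuracy grid
#'   (percent), \code{mean_accuracy}, \code{sd}, fold sizes, seeds, fold
#'   memberships and per-fold selections.
#' @export
run_cv <- function(table, scheme, rand = label_randomization("none"),
                   sel_m = 30L, clf = classifier_spec("lda"),
                   norm_mode = c("train_fitted", "separate")) {
  norm_mode <- match.arg(norm_mode)
  stopifnot(inherits(table, "feature_table"), inherits(scheme, "cv_scheme"),
            inherits(rand, "label_randomization"),
            inherits(clf, "classifier_spec"))
  if (table$normalization_state != "none")
    stopf("run_cv expects an unnormalized table; normalization happens inside each fold")
  run_seeds <- derive_seeds(scheme$seed, scheme$runs)
  acc <- matrix(NA_real_, scheme$runs, scheme$k)
  folds_rec <- vector("list", scheme$runs)
  sel_rec <- vector("list", scheme$runs)
  seeds_rec <- vector("list", scheme$runs)
  for (r in seq_len(scheme$runs)) {
    sub <- derive_seeds(run_seeds[r], 2L)
    seeds_rec[[r]] <- c(run = run_seeds[r], rand = sub[1L], partition = sub[2L])
    tr_table <- randomize_labels(table, rand, seed = sub[1L])
    folds <- if (scheme$mode == "sample_kfold")
      kfold_partition(tr_table, scheme$k, scheme$stratified, sub[2L])
    else
      blockwise_partition(tr_table, scheme$k, scheme$stratified, sub[2L])
    folds_rec[[r]] <- folds
    sel_rec[[r]] <- vector("list", scheme$k)
    for (i in seq_len(scheme$k)) {
      te_idx <- match(folds[[i]], tr_table$meta$sample_id)
      train <- ft_rows(tr_table, -te_idx)
      test <- ft_rows(tr_table, te_idx)
      res <- tryCatch({
        norm <- zscore_fit_apply(train, test, norm_mode)
        sel <- mrmr_select(norm$train, min(sel_m, ncol(norm$train$x)))
        a <- train_eval(clf, ft_cols(norm$train, sel$selected),
                        ft_cols(norm$test, sel$selected))
        list(acc = as.numeric(a), sel = sel$selected)
      }, error = function(e)
        stopf("run %d, fold %d: %s", r, i, conditionMessage(e)))
      acc[r, i] <- res$acc
      sel_rec[[r]][[i]] <- res$sel
    }
  }
  structure(list(scheme = scheme, randomization = rand, clf = clf,
                 sel_m = as.integer(sel_m), norm_mode = norm_mode,
                 accuracies = acc * 100,
                 mean_accuracy = mean(acc) * 100, sd = sd(acc) * 100,
                 n_test_per_fold = lengths(folds_rec[[1L]]),
                 seeds = seeds_rec, folds = folds_rec,
                 selections = sel_rec),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %s, k = %d, runs = %d, labels: %s\n",
              x$scheme$mode, x$scheme$k, x$scheme$runs, x$randomization$level))
  cat(sprintf("  classifier %s, mRMR m = %d, normalization: %s\n",
              x$clf$kind, x$sel_m, x$norm_mode))
  cat(sprintf("  mean accuracy %.2f%% (sd %.2f%%) over %d fold accuracies\n",
              x$mean_accuracy, x$sd, length(x$accuracies)))
  invisible(x)
}

#' @export
summary.cv_result <- function(object, ...) {
  cat(sprintf("Cross-validation summary (%s, labels: %s)\n",
              object$scheme$mode, object$randomization$level))
  cat(sprintf("  mean %.2f%%, sd %.2f%%, fold size(s): %s\n",
              object$mean_accuracy, object$sd,
              paste(unique(object$n_test_per_fold), collapse = "/")))
  per_run <- rowMeans(object$accuracies)
  cat("  per-run means (%):", paste(sprintf("%.2f", per_run), collapse = " "),
      "\n")
  invisible(object)
}

#' @export
plot.cv_result <- function(x, ...) {
  boxplot(t(x$accuracies), xlab = "run", ylab = "fold accuracy (%)",
          main = sprintf("%s, labels: %s", x$scheme$mode,
                         x$randomization$level), ...)
  abline(h = 50, lty = 2)
  invisible(x)
}

#' Serialize a cross-validation result
#'
#' Writes the full result (grid, seeds, fold memberships) as JSON and the
#' per-run-per-fold accuracies as a flat CSV (one row per run x fold).
#'
#' @param result A \code{cv_result}.
#' @param json_path,csv_path Output paths (either may be NULL to skip).
#' @return \code{result}, invisibly.
#' @export
write_cv_result <- function(result, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(result, "cv_result"))
  if (!is.null(json_path)) {
    out <- unclass(result)
    out$scheme <- unclass(out$scheme)
    out$randomization <- unclass(out$randomization)
    out$clf <- unclass(out$clf)
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                         matrix = "rowmajor")
  }
  if (!is.null(csv_path)) {
    grid <- expand.grid(fold = seq_len(result$scheme$k),
                        run = seq_len(result$scheme$runs))[, 2:1]
    grid$accuracy <- as.vector(t(result$accuracies))
    write.csv(grid, csv_path, row.names = FALSE)
  }
  invisible(result)
}
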