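# Independent oracles used to cross-check package computations.  These are
# deliberately straight-line reimplementations sharing no code with the
# package internals.

# Greedy relevance-minus-mean-redundancy selection, plain loops.
brute_force_mrmr <- function(x, y, m) {
  nf <- ncol(x)
  dx <- lapply(seq_len(nf), function(j) {
    s <- stats::sd(x[, j])
    z <- if (s > 0) (x[, j] - mean(x[, j])) / s else rep(0, nrow(x))
    cut(z, c(-Inf, -0.5, 0.5, Inf), labels = FALSE)
  })
  mi <- function(a, b) {
    tb <- table(a, b) / length(a)
    tot <- 0
    for (i in seq_len(nrow(tb))) for (j in seq_len(ncol(tb))) {
      pij <- tb[i, j]
      if (pij > 0)
        tot <- tot + pij * log(pij / (sum(tb[i, ]) * sum(tb[, j])))
    }
    tot
  }
  rel <- sapply(dx, mi, b = y)
  sel <- integer(0)
  for (step in seq_len(m)) {
    best <- -Inf
    pick <- NA
    for (j in seq_len(nf)) {
      if (j %in% sel) next
      score <- rel[j]
      if (length(sel))
        score <- rel[j] - mean(sapply(sel, function(s) mi(dx[[j]], dx[[s]])))
      if (score > best + 1e-12) {
        best <- score
        pick <- j
      }
    }
    sel <- c(sel, pick)
  }
  sel
}

# Labeled toy table exercising informative / near-duplicate / noise /
# weak / constant feature archetypes.
toy_selection_table <- function(seed = 3, n = 60) {
  set.seed(seed)
  y <- rep(c("c1", "c2"), each = n / 2)
  x <- cbind(
    f1 = (y == "c2") * 2 + rnorm(n),
    f2 = (y == "c2") * 2 + rnorm(n, sd = 0.05),
    f3 = rnorm(n),
    f4 = (y == "c2") * 0.8 + rnorm(n),
    f5 = rep(1, n))
  meta <- data.frame(sample_id = sprintf("s%02d", 1:n),
                     trial_id = sprintf("t%02d", rep(1:(n / 4), each = 4)),
                     class_label = y, epoch_index = rep(0:3, n / 4),
                     stringsAsFactors = FALSE)
  rownames(x) <- meta$sample_id
  trialcv:::new_feature_table(x, meta, "toy")
}

# Score one recorded CV run fold-by-fold: scale() by the training half,
# MASS::lda, plain accuracy.  Used against run_cv's recorded fold grids.
straight_line_fold_accuracies <- function(tab, folds) {
  vapply(folds, function(test_ids) {
    te <- match(test_ids, tab$meta$sample_id)
    xtr <- tab$x[-te, , drop = FALSE]
    xte <- tab$x[te, , drop = FALSE]
    mu <- colMeans(xtr)
    s <- apply(xtr, 2, sd)
    xtr <- scale(xtr, center = mu, scale = s)
    xte <- scale(xte, center = mu, scale = s)
    fit <- MASS::lda(xtr, grouping = tab$meta$class_label[-te])
    pred <- as.character(predict(fit, xte)$class)
    100 * mean(pred == tab$meta$class_label[te])
  }, 0)
}
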