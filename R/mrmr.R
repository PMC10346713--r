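# Greedy mRMR feature selection (MID criterion, discrete mutual information
# on 3-bin discretized z-scored features).

# Discretize one feature: z-score by its own mean/sd, 3 bins cut at +/-0.5 SD
# (a constant column collapses to a single bin and carries no information).
discretize3 <- function(x) {
  s <- sd(x)
  z <- if (is.finite(s) && s > 0) (x - mean(x)) / s else rep(0, length(x))
  findInterval(z, c(-0.5, 0.5))
}

# Mutual information (nats) between two discrete vectors.
discrete_mi <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  pa <- rowSums(p)
  pb <- colSums(p)
  idx <- p > 0
  sum(p[idx] * log(p[idx] / outer(pa, pb)[idx]))
}

#' mRMR feature selection on a training table
#'
#' Greedy forward selection with the difference (MID) criterion: at each
#' step the feature maximizing \emph{relevance minus mean redundancy} is
#' added, where relevance is the mutual information between the (3-bin
#' discretized, z-scored) feature and the class label, and redundancy is the
#' mean mutual information with the already-selected features.  The first
#' pick is the maximum-relevance feature.  Ties are broken by the lowest
#' column index, so the result is deterministic given the input column
#' order.
#'
#' @param train A labeled \code{feature_table} (two or more classes).
#' @param m Target number of features (>= 1).  If \code{m >= n_features} all
#'   features are returned in relevance order (with a warning when
#'   \code{m > n_features}).
#' @return An object of class \code{selection_result}: list with ordered
#'   \code{selected} column indices, per-step criterion \code{scores}, and
#'   \code{m}.
#' @export
mrmr_select <- function(train, m) {
  stopifnot(inherits(train, "feature_table"))
  if (!is_count(m) || m < 1) stopf("m must be a positive integer")
  y <- train$meta$class_label
  if (length(unique(y)) < 2L)
    stopf("mRMR requires a labeled training set with at least 2 classes")
  nf <- ncol(train$x)
  disc <- apply(train$x, 2L, discretize3)
  rel <- vapply(seq_len(nf), function(j) discrete_mi(disc[, j], y), 0)

  if (m >= nf) {
    if (m > nf) warnf("m (%d) exceeds the number of features (%d); selecting all",
                      m, nf)
    ord <- order(-rel, seq_len(nf))
    return(structure(list(selected = ord, scores = rel[ord], m = nf),
                     class = "selection_result"))
  }

  selected <- integer(0)
  scores <- numeric(0)
  red <- matrix(NA_real_, nf, nf)           # memoized pairwise MI
  for (step in seq_len(m)) {
    cand <- setdiff(seq_len(nf), selected)
    crit <- vapply(cand, function(j) {
      if (!length(selected)) return(rel[j])
      r <- vapply(selected, function(s) {
        if (is.na(red[j, s]))
          red[j, s] <<- red[s, j] <<- discrete_mi(disc[, j], disc[, s])
        red[j, s]
      }, 0)
      rel[j] - mean(r)
    }, 0)
    best <- cand[order(-crit, cand)[1L]]
    selected <- c(selected, best)
    scores <- c(scores, crit[match(best, cand)])
  }
  structure(list(selected = selected, scores = scores, m = as.integer(m)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result: %d features selected (m = %d)\n",
              length(x$selected), x$m))
  cat("  indices:", paste(x$selected, collapse = " "), "\n")
  invisible(x)
}
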