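# Statistical comparison of CV accuracies against ground truth and chance,
# and the report grid across scenarios.

new_stat_result <- function(comparison, d, n) {
  m <- mean(d)
  s <- sd(d)
  if (s == 0) {                     # degenerate: convention t = 0, p = 1
    t_stat <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
  } else {
    t_stat <- m / (s / sqrt(n))
    p <- 2 * pt(-abs(t_stat), n - 1)
  }
  structure(list(comparison = comparison, t_stat = t_stat, df = n - 1L,
                 p_value = p, mean_difference = m, n = as.integer(n)),
            class = "stat_result")
}

#' Paired t-test between two accuracy vectors
#'
#' Two-sided paired t-test on the differences \code{a - b}, paired by
#' replicate (or subject).  Zero-variance, zero-mean differences give
#' \code{t = 0, p = 1} by convention.
#'
#' @param a,b Equal-length accuracy vectors (percent), length >= 2.
#' @return Object of class \code{stat_result} with fields \code{t_stat},
#'   \code{df}, \code{p_value}, \code{mean_difference} (percentage points)
#'   and \code{n}.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) stopf("a and b must have equal length")
  if (length(a) < 2L) stopf("need at least 2 pairs")
  new_stat_result("paired_vs_gt", a - b, length(a))
}

#' One-sample t-test of accuracies against a chance level
#'
#' Two-sided one-sample t-test of \code{a} against \code{mu} (50 for binary
#' classification).  All values equal to \code{mu} give \code{t = 0, p = 1}.
#'
#' @param a Accuracy vector (percent), length >= 2.
#' @param mu Chance level in percent (default 50).
#' @return Object of class \code{stat_result}.
#' @export
one_sample_ttest <- function(a, mu = 50) {
  if (length(a) < 2L) stopf("need at least 2 values")
  new_stat_result("one_sample_vs_chance", a - mu, length(a))
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: t = %.4g, df = %d, p = %.4g, mean difference = %.3g (n = %d)\n",
              x$comparison, x$t_stat, x$df, x$p_value, x$mean_difference, x$n))
  invisible(x)
}

# Cells compared to the scenario's ground truth via paired t-tests vs cells
# compared to chance via one-sample t-tests.
GT_CELLS <- c("kfold", "block")
CHANCE_CELLS <- c("tr_kfold", "tr_block", "sr_kfold", "rand")

#' Build the scenario report grid
#'
#' Aggregates per-replicate CV accuracies into the report grid: for every
#' scenario (separability level x classifier x feature set) and section,
#' the true-label k-fold and block-wise cells are compared to that
#' scenario's ground truth (the 1-epoch-per-trial section) via paired
#' t-tests across replicates, and the label-randomized cells are compared
#' to chance (50\%) via one-sample t-tests.  Significance flags derive only
#' from these tests at the stated alpha; direction is the sign of the mean
#' difference.
#'
#' @param results Data.frame with columns \code{replicate},
#'   \code{separability}, \code{section}, \code{classifier},
#'   \code{feature_set}, \code{test} (one of \code{gt}, \code{rand},
#'   \code{kfold}, \code{block}, \code{tr_kfold}, \code{tr_block},
#'   \code{sr_kfold}) and \code{accuracy} (percent).
#' @param alpha Significance level (default 0.05).
#' @param p_adjust \code{"none"} (default; individual per-scenario tests) or
#'   \code{"holm"} for a family-wise correction across all cells.
#' @return Object of class \code{scenario_report}: a data.frame with one
#'   row per cell (mean accuracy, reference, mean difference, t, df, p,
#'   significance flag, direction) and attribute \code{alpha}.
#' @export
build_report <- function(results, alpha = 0.05, p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  need <- c("replicate", "separability", "section", "classifier",
            "feature_set", "test", "accuracy")
  if (!all(need %in% names(results)))
    stopf("results is missing column(s): %s",
          paste(setdiff(need, names(results)), collapse = ", "))
  scen_key <- function(df) paste(df$separability, df$classifier,
                                 df$feature_set, sep = " / ")
  gt <- results[results$test == "gt", ]
  missing_gt <- setdiff(unique(scen_key(results)), unique(scen_key(gt)))
  if (length(missing_gt))
    stopf("no ground-truth condition for scenario(s): %s",
          paste(missing_gt, collapse = "; "))

  cells <- unique(results[c("separability", "section", "classifier",
                            "feature_set", "test")])
  cells <- cells[order(cells$separability, cells$classifier,
                       cells$feature_set, cells$section,
                       match(cells$test,
                             c("gt", "kfold", "block", "tr_kfold",
                               "tr_block", "sr_kfold", "rand"))), ]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    ci <- cells[i, ]
    sel <- results$separability == ci$separability &
      results$section == ci$section & results$classifier == ci$classifier &
      results$feature_set == ci$feature_set & results$test == ci$test
    sub <- results[sel, ]
    sub <- sub[order(sub$replicate), ]
    base <- data.frame(ci, mean_accuracy = mean(sub$accuracy),
                       row.names = NULL, stringsAsFactors = FALSE)
    if (ci$test %in% GT_CELLS) {
      g <- gt[scen_key(gt) == scen_key(ci), ]
      g <- g[order(g$replicate), ]
      stopifnot(identical(g$replicate, sub$replicate))
      st <- paired_ttest(sub$accuracy, g$accuracy)
      ref <- mean(g$accuracy)
    } else if (ci$test %in% CHANCE_CELLS) {
      st <- one_sample_ttest(sub$accuracy, 50)
      ref <- 50
    } else {                                    # the ground-truth cell itself
      st <- NULL
      ref <- NA_real_
    }
    cbind(base, data.frame(
      reference = ref,
      mean_diff = if (is.null(st)) NA_real_ else st$mean_difference,
      t_stat = if (is.null(st)) NA_real_ else st$t_stat,
      df = if (is.null(st)) NA_integer_ else st$df,
      p_value = if (is.null(st)) NA_real_ else st$p_value))
  })
  out <- do.call(rbind, rows)
  if (p_adjust == "holm")
    out$p_value <- stats::p.adjust(out$p_value, "holm")
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out$direction <- ifelse(is.na(out$mean_diff) | out$mean_diff == 0, "none",
                          ifelse(out$mean_diff > 0, "over", "under"))
  out$direction[!out$significant & is.na(out$mean_diff)] <- "none"
  rownames(out) <- NULL
  structure(out, alpha = alpha, p_adjust = p_adjust,
            class = c("scenario_report", "data.frame"))
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("scenario_report: %d cells, alpha = %g (p adjust: %s)\n",
              nrow(x), attr(x, "alpha"), attr(x, "p_adjust")))
  df <- as.data.frame(x)
  df$mean_accuracy <- sprintf("%.2f", df$mean_accuracy)
  df$flag <- ifelse(df$significant, paste0("*", df$direction), "")
  print(df[c("separability", "section", "classifier", "feature_set", "test",
             "mean_accuracy", "flag")], row.names = FALSE)
  invisible(x)
}

#' Serialize a scenario report
#'
#' Writes the report grid as CSV and, optionally, a JSON document carrying
#' the full test statistics and the alpha level.
#'
#' @param report A \code{scenario_report}.
#' @param csv_path,json_path Output paths (either may be NULL to skip).
#' @return \code{report}, invisibly.
#' @export
write_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "scenario_report"))
  if (!is.null(csv_path))
    write.csv(as.data.frame(report), csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(alpha = attr(report, "alpha"),
                              p_adjust = attr(report, "p_adjust"),
                              cells = as.data.frame(report)),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(report)
}
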