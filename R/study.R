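# Experiment planning and end-to-end execution of the factorial study on
# synthetic sessions, mirroring the three-section (5/15/60 s trial length)
# design.

TEST_MODES <- list(
  gt       = list(mode = "sample_kfold",   rand = "none"),
  rand     = list(mode = "sample_kfold",   rand = "trial"),
  kfold    = list(mode = "sample_kfold",   rand = "none"),
  block    = list(mode = "trial_blockwise", rand = "none"),
  tr_kfold = list(mode = "sample_kfold",   rand = "trial"),
  sr_kfold = list(mode = "sample_kfold",   rand = "sample"),
  tr_block = list(mode = "trial_blockwise", rand = "trial"))

#' Configure a factorial cross-validation study
#'
#' Describes the full experiment: the separability levels (generator deltas),
#' feature sets and classifiers to cross, the trial-length sections, the
#' generator knobs and the CV settings.  For a section whose trials hold a
#' single epoch, two tests are planned (true labels and randomized labels;
#' k-fold and block-wise CV coincide there, as do the two randomization
#' levels, and the true-label test is the ground-truth condition).  For
#' multi-epoch sections five tests are planned: true-label k-fold and
#' block-wise CV, plus trial-randomized k-fold, sample-randomized k-fold
#' and trial-randomized block-wise CV.
#'
#' The default separability deltas were calibrated once against
#' [bayes_rate_oracle()] so that the high and low levels sit near 93\% and
#' 64\% best achievable single-epoch accuracy under the default generator.
#'
#' @param profile \code{"reduced"} (small montage and factor lists; suited
#'   to interactive use and continuous testing) or \code{"paper"} (full
#'   factor lists: 2 separability levels x 4 feature sets x 3 classifiers,
#'   12 replicates).
#' @param ... Overrides for any configuration field.  Notably
#'   \code{section_tests} may name an explicit test list per section (e.g.
#'   \code{list(T60 = "kfold")}) in place of the default per-section rule.
#' @return Object of class \code{study_config} (a named list).
#' @export
study_config <- function(profile = c("reduced", "paper"), ...) {
  profile <- match.arg(profile)
  cfg <- list(
    profile = profile,
    separability = c(high = 0.215, low = 0.05),
    feature_sets = c("bandpower", "spectral_entropy", "rms", "variance"),
    classifiers = c("lda", "linear_svm", "knn"),
    trial_durations_s = c(5, 15, 60),
    minutes_per_class = 6,
    epoch_duration_s = 5,
    fs = 128L,
    n_channels = 4L,
    effect_bands = "alpha",
    trial_gain_sd = 0.3,
    noise_sd = 1,
    k = 6L,
    runs = 5L,
    sel_m = 30L,
    norm_mode = "train_fitted",
    n_replicates = 12L,
    alpha = 0.05,
    section_tests = NULL)
  if (profile == "reduced") {
    cfg$feature_sets <- "bandpower"
    cfg$classifiers <- "lda"
    cfg$runs <- 2L
    cfg$n_replicates <- 2L
  }
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stopf("unknown study_config field(s): %s",
                         paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf("study_config (%s): %d separability x %d feature sets x %d classifiers, sections %s\n",
              x$profile, length(x$separability), length(x$feature_sets),
              length(x$classifiers),
              paste0("T", x$trial_durations_s, collapse = "/")))
  cat(sprintf("  generator: %d ch @ %d Hz, %g min/class, tau = %g, sigma = %g, deltas = %s\n",
              x$n_channels, x$fs, x$minutes_per_class, x$trial_gain_sd,
              x$noise_sd, paste(sprintf("%s: %g", names(x$separability),
                                        x$separability), collapse = ", ")))
  cat(sprintf("  CV: k = %d, runs = %d, mRMR m = %d, norm = %s, replicates = %d\n",
              x$k, x$runs, x$sel_m, x$norm_mode, x$n_replicates))
  invisible(x)
}

section_tests <- function(trial_duration_s, epoch_duration_s) {
  if (trial_duration_s / epoch_duration_s <= 1) c("gt", "rand")
  else c("kfold", "block", "tr_kfold", "sr_kfold", "tr_block")
}

#' Enumerate the experiment plan
#'
#' Expands the study factors into the full grid of scenarios (separability
#' level x feature set x classifier) and, per scenario, the per-section CV
#' tests.  Every test row carries a seed deterministically derived from the
#' master seed, so a serialized plan replays exactly.
#'
#' @param config A [study_config()].
#' @param master_seed Integer master seed (default 1).
#' @return Object of class \code{experiment_plan}: list with the
#'   \code{scenarios} grid, the \code{tests} table, counts
#'   (\code{n_scenarios}, \code{total_tests}) and the master seed.
#' @export
plan_experiment <- function(config, master_seed = 1L) {
  stopifnot(inherits(config, "study_config"))
  if (!length(config$separability) || !length(config$feature_sets) ||
      !length(config$classifiers) || !length(config$trial_durations_s))
    stopf("empty factor list in study configuration")
  scenarios <- expand.grid(separability = names(config$separability),
                           feature_set = config$feature_sets,
                           classifier = config$classifiers,
                           stringsAsFactors = FALSE)
  sect <- do.call(rbind, lapply(config$trial_durations_s, function(d) {
    nm <- sprintf("T%g", d)
    tests <- config$section_tests[[nm]] %||%
      section_tests(d, config$epoch_duration_s)
    bad <- setdiff(tests, names(TEST_MODES))
    if (length(bad)) stopf("unknown CV test(s): %s", paste(bad, collapse = ", "))
    data.frame(section = nm, trial_duration_s = d, test = tests,
               stringsAsFactors = FALSE)
  }))
  tests <- merge(scenarios, sect, by = NULL)
  tests <- tests[order(tests$separability, tests$classifier,
                       tests$feature_set, tests$trial_duration_s,
                       match(tests$test, names(TEST_MODES))), ]
  rownames(tests) <- NULL
  tests$seed <- derive_seeds(master_seed, nrow(tests))
  structure(list(scenarios = scenarios, tests = tests,
                 n_scenarios = nrow(scenarios),
                 tests_per_scenario = nrow(sect),
                 total_tests = nrow(tests),
                 master_seed = as.integer(master_seed),
                 config = config),
            class = "experiment_plan")
}

#' @export
print.experiment_plan <- function(x, ...) {
  cat(sprintf("experiment_plan: %d scenarios x %d tests = %d CV tests per replicate (master seed %d)\n",
              x$n_scenarios, x$tests_per_scenario, x$total_tests,
              x$master_seed))
  invisible(x)
}

#' Run the full factorial study on synthetic sessions
#'
#' For each replicate ("synthetic participant"): one session is generated
#' per separability level and section, segmented into epochs, and converted
#' to the configured feature tables; every planned CV test is then executed
#' with [run_cv()].  Results are aggregated across replicates into a
#' [build_report()] grid.  With \code{out_dir}, per-replicate results are
#' persisted as CSV and a completed replicate is skipped on re-run (resume
#' support); a manifest captures the configuration and seeds.
#'
#' @param config A [study_config()].
#' @param n_replicates Number of replicates (default from the config).
#' @param master_seed Integer master seed.
#' @param out_dir Optional results directory.
#' @return Object of class \code{study_result}: list with \code{results}
#'   (long data.frame of per-replicate accuracies), \code{report}
#'   (a \code{scenario_report}) and \code{plan}.
#' @export
run_study <- function(config, n_replicates = config$n_replicates,
                      master_seed = 1L, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  plan <- plan_experiment(config, master_seed)
  rep_seeds <- derive_seeds(master_seed + 1L, n_replicates)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  all_res <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    rep_file <- if (!is.null(out_dir))
      file.path(out_dir, sprintf("replicate%03d.csv", r))
    if (!is.null(rep_file) && file.exists(rep_file)) {
      all_res[[r]] <- read.csv(rep_file, stringsAsFactors = FALSE)
      next
    }
    all_res[[r]] <- run_replicate(plan, r, rep_seeds[r])
    if (!is.null(rep_file))
      write.csv(all_res[[r]], rep_file, row.names = FALSE)
  }
  results <- do.call(rbind, all_res)
  report <- build_report(results, alpha = config$alpha)
  if (!is.null(out_dir)) {
    write_report(report, csv_path = file.path(out_dir, "report.csv"),
                 json_path = file.path(out_dir, "report.json"))
    manifest <- list(master_seed = master_seed, n_replicates = n_replicates,
                     replicate_seeds = rep_seeds,
                     config = unclass(config),
                     package_version =
                       as.character(utils::packageVersion("trialcv")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(results = results, report = report, plan = plan),
            class = "study_result")
}

run_replicate <- function(plan, replicate, rep_seed) {
  config <- plan$config
  sections <- sprintf("T%g", config$trial_durations_s)
  sess_seeds <- matrix(derive_seeds(rep_seed,
                                    length(config$separability) *
                                      length(sections)),
                       length(config$separability), length(sections),
                       dimnames = list(names(config$separability), sections))
  tables <- lapply(names(config$separability), function(lvl) {
    out <- lapply(seq_along(sections), function(si) {
      sc <- session_config(minutes_per_class = config$minutes_per_class,
                           trial_duration_s = config$trial_durations_s[si],
                           epoch_duration_s = config$epoch_duration_s,
                           fs = config$fs, n_channels = config$n_channels,
                           delta = config$separability[[lvl]],
                           effect_bands = config$effect_bands,
                           trial_gain_sd = config$trial_gain_sd,
                           noise_sd = config$noise_sd,
                           seed = sess_seeds[lvl, si])
      epochs <- segment_trials(generate_session(sc))
      fts <- lapply(config$feature_sets, function(fset)
        build_feature_table(epochs, fset))
      names(fts) <- config$feature_sets
      fts
    })
    names(out) <- sections
    out
  })
  names(tables) <- names(config$separability)

  rows <- lapply(seq_len(nrow(plan$tests)), function(i) {
    tt <- plan$tests[i, ]
    table <- tables[[tt$separability]][[tt$section]][[tt$feature_set]]
    tm <- TEST_MODES[[tt$test]]
    seed_r <- derive_seeds(tt$seed, max(replicate, 1L))[replicate]
    res <- run_cv(table,
                  cv_scheme(tm$mode, k = plan$config$k,
                            runs = plan$config$runs, seed = seed_r),
                  rand = label_randomization(tm$rand),
                  sel_m = min(plan$config$sel_m, ncol(table$x)),
                  clf = classifier_spec(tt$classifier),
                  norm_mode = plan$config$norm_mode)
    data.frame(replicate = replicate, separability = tt$separability,
               section = tt$section, classifier = tt$classifier,
               feature_set = tt$feature_set, test = tt$test,
               accuracy = res$mean_accuracy, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("study_result: %d replicates, %d CV tests per replicate\n",
              length(unique(x$results$replicate)), x$plan$total_tests))
  print(x$report)
  invisible(x)
}
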