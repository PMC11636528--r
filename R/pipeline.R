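#' Pooled imaging feature blocks for a cohort
#'
#' Computes the per-subject ISC maps (against the cohort's reference
#' group) and pools them and the grey-matter volumes region-wise into the
#' eight imaging blocks (`vbm_min` ... `isc_sd`).
#'
#' @param cohort a `cohort_bundle`.
#' @param modalities subset of `c("vbm", "isc")`.
#' @return named list of subjects x regions matrices.
#' @export
compute_imaging_blocks <- function(cohort, modalities = c("vbm", "isc")) {
  stopifnot(inherits(cohort, "cohort_bundle"))
  modalities <- match.arg(modalities, c("vbm", "isc"), several.ok = TRUE)
  atlas <- cohort$volumes$atlas
  r <- cohort$config$n_regions
  blocks <- list()
  if ("vbm" %in% modalities)
    blocks <- c(blocks, pool_subject_maps(cohort$volumes$vbm, atlas,
                                          "vbm", r))
  if ("isc" %in% modalities) {
    isc_maps <- compute_cohort_isc(cohort)
    blocks <- c(blocks, pool_subject_maps(isc_maps, atlas, "isc", r))
  }
  blocks
}

#' Run the full multimodal prediction analysis on a cohort
#'
#' Computes the selected feature modalities, runs randomized-pair
#' cross-validation with per-run retraining, summarizes accuracy (mean
#' with a bootstrap confidence interval, and ensemble-voted per-subject
#' labels with confusion metrics), and assesses significance by re-running
#' the cross-validation under permuted labels. All stages derive their
#' seeds from `seed`, so the whole analysis is reproducible from one
#' integer.
#'
#' @param cohort a `cohort_bundle`.
#' @param modalities subset of `c("clinical", "vbm", "isc")`.
#' @param model `"nn"` or `"svm"`.
#' @param n_runs cross-validation runs for the true-label analysis
#'   (full scale: 2000).
#' @param train_cfg a [train_config()].
#' @param n_perm label permutations (full scale: 1000); 0 skips the
#'   permutation test.
#' @param n_runs_perm cross-validation runs per permutation (defaults to
#'   `n_runs`; smaller values trade permutation-distribution resolution
#'   for speed).
#' @param n_boot bootstrap resamples for the accuracy CI.
#' @param seed master seed.
#' @param collect_relevance record LRP relevance per run and aggregate an
#'   importance report (NN only).
#' @param univariate include the univariate clinical group table.
#' @return a `trs_report`: list with `runs`, `mean_accuracy`, `voted`,
#'   `metrics`, `permutation`, optional `importance` and `univariate`,
#'   and `config` echoing every resolved parameter.
#' @export
run_analysis <- function(cohort, modalities = c("clinical", "vbm", "isc"),
                         model = c("nn", "svm"), n_runs = 2000L,
                         train_cfg = train_config(), n_perm = 1000L,
                         n_runs_perm = n_runs, n_boot = 10000L, seed = 1L,
                         collect_relevance = FALSE, univariate = FALSE) {
  stopifnot(inherits(cohort, "cohort_bundle"))
  model <- match.arg(model)
  modalities <- match.arg(modalities, c("clinical", "vbm", "isc"),
                          several.ok = TRUE)
  labels <- cohort$labels
  clinical <- if ("clinical" %in% modalities) cohort$clinical else NULL
  imaging_sel <- intersect(c("vbm", "isc"), modalities)
  imaging <- if (length(imaging_sel) > 0)
    compute_imaging_blocks(cohort, imaging_sel) else NULL

  stage_seeds <- withr::with_seed(seed, sample.int(2^31 - 1, 4))

  runs <- run_pairwise_cv(labels, clinical = clinical, imaging = imaging,
                          model = model, n_runs = n_runs,
                          train_cfg = train_cfg, seed = stage_seeds[1],
                          collect_relevance = collect_relevance)
  acc <- mean_accuracy_with_ci(runs, n_boot = n_boot, seed = stage_seeds[2])
  voted <- vote_labels(runs, labels)
  metrics <- confusion_metrics(voted)

  permutation <- NULL
  if (n_perm > 0) {
    stat_fn <- function(perm_labels) {
      mean(run_pairwise_cv(perm_labels, clinical = clinical,
                           imaging = imaging, model = model,
                           n_runs = n_runs_perm, train_cfg = train_cfg,
                           seed = stage_seeds[3])$runs$accuracy)
    }
    permutation <- permutation_pvalue(stat_fn, labels,
                                      observed = acc$mean, n_perm = n_perm,
                                      seed = stage_seeds[4])
  }

  importance <- if (collect_relevance && model == "nn")
    aggregate_importance(runs) else NULL
  uni <- if (univariate) univariate_table(cohort$clinical, labels) else NULL

  structure(list(
    runs = runs, mean_accuracy = acc, voted = voted, metrics = metrics,
    permutation = permutation, importance = importance, univariate = uni,
    model = model, modalities = modalities,
    config = list(modalities = modalities, model = model, n_runs = n_runs,
                  n_perm = n_perm, n_runs_perm = n_runs_perm,
                  n_boot = n_boot, seed = seed,
                  train = unclass(train_cfg),
                  cohort = unclass(cohort$config))),
    class = "trs_report")
}

#' @export
print.trs_report <- function(x, ...) {
  cat(sprintf("Multimodal prediction report (%s, modalities: %s)\n",
              toupper(x$model), paste(x$modalities, collapse = "+")))
  cat(sprintf("  mean accuracy over %d runs: %.2f %% (95 %% CI [%.2f, %.2f])\n",
              x$mean_accuracy$n_runs, x$mean_accuracy$mean,
              x$mean_accuracy$ci[1], x$mean_accuracy$ci[2]))
  cat(sprintf("  voted: accuracy %.2f %%, sensitivity %.2f %%, specificity %.2f %%, precision %.2f %%\n",
              x$metrics[["accuracy"]], x$metrics[["sensitivity"]],
              x$metrics[["specificity"]], x$metrics[["precision"]]))
  cat(sprintf("  confusion: TP=%d FN=%d TN=%d FP=%d\n",
              x$voted$confusion[["TP"]], x$voted$confusion[["FN"]],
              x$voted$confusion[["TN"]], x$voted$confusion[["FP"]]))
  if (!is.null(x$permutation))
    cat(sprintf("  permutation p = %.6g (%d permutations)\n",
                x$permutation$p.value, x$permutation$n_perm))
  invisible(x)
}
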