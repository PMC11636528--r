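#' Mean cross-validation accuracy with a bootstrap confidence interval
#'
#' The point estimate is the mean of the per-run accuracies (each 0, 50 or
#' 100). The confidence interval is a percentile bootstrap over runs.
#'
#' @param runs a `run_set` (or a numeric vector of per-run accuracies).
#' @param n_boot bootstrap resamples (the full-scale analysis uses 10 000).
#' @param level confidence level.
#' @param seed integer seed for the resampling.
#' @return list with `mean`, `ci` (length-2 vector), `n_runs`, `n_boot`.
#' @export
mean_accuracy_with_ci <- function(runs, n_boot = 10000L, level = 0.95,
                                  seed = 1L) {
  acc <- if (inherits(runs, "run_set")) runs$runs$accuracy else as.numeric(runs)
  if (length(acc) < 1) stop("empty run set")
  boot_means <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i)
      mean(acc[sample.int(length(acc), replace = TRUE)]), numeric(1))
  })
  alpha <- (1 - level) / 2
  list(mean = mean(acc),
       ci = unname(stats::quantile(boot_means, c(alpha, 1 - alpha))),
       n_runs = length(acc), n_boot = n_boot)
}

#' Permutation p-value for a label-dependent statistic
#'
#' Re-runs the supplied analysis closure on label vectors shuffled
#' uniformly at random and compares the observed statistic to the permuted
#' ones. Uses the add-one convention `p = (1 + k) / (1 + n_perm)` with
#' `k` the number of permuted statistics at least as large as the observed
#' one, so the smallest attainable p with 1000 permutations is
#' 1/1001 = 0.000999.
#'
#' @param stat_fn function taking a label vector and returning a scalar
#'   statistic (e.g. the mean CV accuracy of a full re-analysis under those
#'   labels).
#' @param labels the true label vector.
#' @param observed the observed statistic; if `NULL`, computed as
#'   `stat_fn(labels)`.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed for the shuffles.
#' @return list with `p.value`, `observed`, `permuted` (vector), `n_perm`.
#' @export
permutation_pvalue <- function(stat_fn, labels, observed = NULL,
                               n_perm = 1000L, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (is.null(observed)) observed <- stat_fn(labels)
  permuted <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) stat_fn(sample(labels)), numeric(1))
  })
  p <- (1 + sum(permuted >= observed)) / (1 + n_perm)
  list(p.value = p, observed = observed, permuted = permuted,
       n_perm = n_perm)
}

#' Two-sided permutation comparison of two analyses
#'
#' Compares the absolute difference in mean accuracy between two run sets
#' to its permutation distribution obtained by randomly shuffling the
#' per-run accuracies between the two analyses (preserving the group
#' sizes). Same add-one convention and 1/(n_perm+1) floor as
#' [permutation_pvalue()].
#'
#' @param runs_a,runs_b `run_set` objects or numeric accuracy vectors.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @return list with `p.value`, `observed` (absolute mean difference),
#'   `permuted`, `n_perm`.
#' @export
compare_analyses <- function(runs_a, runs_b, n_perm = 1000L, seed = 1L) {
  acc_a <- if (inherits(runs_a, "run_set")) runs_a$runs$accuracy
           else as.numeric(runs_a)
  acc_b <- if (inherits(runs_b, "run_set")) runs_b$runs$accuracy
           else as.numeric(runs_b)
  if (length(acc_a) < 1 || length(acc_b) < 1) stop("empty run set")
  observed <- abs(mean(acc_a) - mean(acc_b))
  pooled <- c(acc_a, acc_b)
  na <- length(acc_a)
  permuted <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      pick <- sample.int(length(pooled), na)
      abs(mean(pooled[pick]) - mean(pooled[-pick]))
    }, numeric(1))
  })
  p <- (1 + sum(permuted >= observed)) / (1 + n_perm)
  list(p.value = p, observed = observed, permuted = permuted,
       n_perm = n_perm)
}
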