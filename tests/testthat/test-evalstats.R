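test_that("randomized-pair splits balance training by majority subsampling", {
  labels <- c(rep(1L, 7), rep(0L, 31))  # 7 vs 31
  sp <- draw_cv_split(labels, seed = 3)
  expect_identical(labels[sp$test_pos], 1L)
  expect_identical(labels[sp$test_neg], 0L)
  expect_identical(sum(labels[sp$train] == 1), 6L)
  expect_identical(sum(labels[sp$train] == 0), 6L)
  expect_length(sp$omitted, 24L)  # 30 remaining negatives minus 6 kept
  expect_length(intersect(c(sp$test_pos, sp$test_neg), sp$train), 0L)
  # balanced cohort: nothing omitted
  sp2 <- draw_cv_split(rep(c(1L, 0L), 5), seed = 1)
  expect_length(sp2$train, 8L)
  expect_length(sp2$omitted, 0L)
  # determinism
  expect_identical(draw_cv_split(rep(c(1L, 0L), 5), seed = 9),
                   draw_cv_split(rep(c(1L, 0L), 5), seed = 9))
  expect_error(draw_cv_split(c(1L, 0L, 0L, 0L)), "at least 2")
})

test_that("per-run accuracy is confined to {0, 50, 100} and reproducible", {
  coh <- generate_cohort(tiny_config(seed = 4))
  blocks <- compute_imaging_blocks(coh, "vbm")
  rs <- run_pairwise_cv(coh$labels, clinical = coh$clinical,
                        imaging = blocks, model = "nn", n_runs = 6,
                        train_cfg = train_config(iterations = 50), seed = 2)
  expect_true(all(rs$runs$accuracy %in% c(0, 50, 100)))
  rs2 <- run_pairwise_cv(coh$labels, clinical = coh$clinical,
                         imaging = blocks, model = "nn", n_runs = 6,
                         train_cfg = train_config(iterations = 50), seed = 2)
  expect_identical(rs$runs, rs2$runs)
  # svm path produces the same record structure
  rs_svm <- run_pairwise_cv(coh$labels, clinical = coh$clinical,
                            imaging = blocks, model = "svm", n_runs = 6,
                            seed = 2)
  expect_true(all(rs_svm$runs$accuracy %in% c(0, 50, 100)))
})

test_that("mean accuracy and bootstrap CI behave on known inputs", {
  expect_equal(mean_accuracy_with_ci(c(0, 50, 100, 50), n_boot = 50,
                                     seed = 1)$mean, 50)
  const <- mean_accuracy_with_ci(rep(75, 40), n_boot = 200, seed = 1)
  expect_equal(const$ci, c(75, 75))
  # bootstrap CI of a {0,100} coin brackets 50
  two <- mean_accuracy_with_ci(rep(c(0, 100), 100), n_boot = 2000, seed = 2)
  expect_lt(two$ci[1], 50)
  expect_gt(two$ci[2], 50)
  expect_error(mean_accuracy_with_ci(numeric(0)), "empty")
})

test_that("permutation p follows the add-one convention and its floor", {
  # contrived deterministic statistic driven by the label ordering
  w <- seq_along(1:10)
  stat_fn <- function(l) sum(l * w)
  labels <- c(rep(0L, 5), rep(1L, 5))  # observed stat is the maximum: 40
  res <- permutation_pvalue(stat_fn, labels, n_perm = 200, seed = 1)
  expect_gte(res$p.value, 1 / 201)
  # observed above every permuted value -> exactly the floor
  res_hi <- permutation_pvalue(stat_fn, labels, observed = 1e6,
                               n_perm = 200, seed = 1)
  expect_equal(res_hi$p.value, 1 / 201)
  # observed below every permuted value -> p = 1
  res_lo <- permutation_pvalue(stat_fn, labels, observed = -1,
                               n_perm = 200, seed = 1)
  expect_equal(res_lo$p.value, 1)
  # (1 + k) / (1 + P): 3 permutations with exactly one >= observed -> 0.5
  queue <- c(10, -5, -7)
  i <- 0
  stat_queue <- function(l) { i <<- i + 1; queue[i] }
  res3 <- permutation_pvalue(stat_queue, labels, observed = 5, n_perm = 3,
                             seed = 1)
  expect_equal(res3$p.value, 0.5)
  expect_error(permutation_pvalue(stat_fn, labels, n_perm = 0), "n_perm")
})

test_that("two-analysis comparison reaches p = 1 and the 0.000999 floor", {
  a <- rep(c(0, 50, 100), 20)
  same <- compare_analyses(a, a, n_perm = 100, seed = 1)
  expect_equal(same$p.value, 1)
  apart <- compare_analyses(rep(100, 50), rep(0, 50), n_perm = 1000,
                            seed = 2)
  expect_equal(apart$p.value, 1 / 1001)
  expect_equal(round(apart$p.value, 6), 0.000999)
  expect_error(compare_analyses(numeric(0), a), "empty")
})

test_that("hard voting follows majorities, breaks ties positive, flags untested", {
  runs <- structure(list(runs = data.frame(
    run = 1:4,
    test_pos = c(1L, 1L, 1L, 2L),
    test_neg = c(3L, 3L, 4L, 4L),
    pred_pos = c(1L, 0L, 1L, 0L),
    pred_neg = c(0L, 1L, 1L, 1L),
    accuracy = c(100, 0, 50, 0)),
    model = "nn", n_runs = 4L, seed = 1L,
    subject_ids = sprintf("s%d", 1:5)), class = "run_set")
  truth <- c(1L, 1L, 0L, 0L, 0L)
  expect_warning(v <- vote_labels(runs, truth), "never appeared")
  expect_identical(v$voted[1], 1L)   # 2 of 3 votes positive
  expect_identical(v$voted[2], 0L)
  expect_identical(v$voted[3], 1L)   # 1 vs 1 tie resolves positive
  expect_identical(v$appearances[3], 2L)
  expect_true(is.na(v$voted[5]))
  expect_identical(sum(v$confusion), 4L)  # untested subject excluded
  # explicit tie: one positive and one negative vote -> positive class
  runs$runs <- data.frame(run = 1:2, test_pos = c(1L, 1L),
                          test_neg = c(2L, 2L), pred_pos = c(1L, 0L),
                          pred_neg = c(0L, 0L), accuracy = c(100, 50))
  v2 <- vote_labels(runs, truth = c(1L, 0L))
  expect_identical(v2$voted[1], 1L)
})

test_that("confusion metrics reproduce standard formulas and guard zeros", {
  perfect <- confusion_metrics(c(TP = 7, FN = 0, TN = 31, FP = 0))
  expect_true(all(perfect == 100))
  none <- confusion_metrics(c(TP = 0, FN = 5, TN = 10, FP = 0))
  expect_true(is.na(none[["precision"]]))  # 0/0 reported as NA, not 0
  expect_error(confusion_metrics(c(TP = 0, FN = 0, TN = 0, FP = 0)),
               "zero")
  expect_error(confusion_metrics(c(TP = -1, FN = 0, TN = 1, FP = 0)),
               "negative")
})

test_that("voted accuracy equals confusion-derived accuracy on real runs", {
  coh <- generate_cohort(tiny_config(seed = 10))
  blocks <- compute_imaging_blocks(coh, "vbm")
  rs <- run_pairwise_cv(coh$labels, imaging = blocks, model = "svm",
                        n_runs = 40, seed = 3)
  v <- vote_labels(rs, coh$labels)
  m <- confusion_metrics(v)
  ok <- !is.na(v$voted)
  expect_equal(m[["accuracy"]],
               round(100 * mean(v$voted[ok] == coh$labels[ok]), 2))
})

test_that("importance aggregation sums relevance toward the true class", {
  coh <- generate_cohort(tiny_config(seed = 12))
  blocks <- compute_imaging_blocks(coh)
  rs <- run_pairwise_cv(coh$labels, clinical = coh$clinical,
                        imaging = blocks, model = "nn", n_runs = 3,
                        train_cfg = train_config(iterations = 50), seed = 7,
                        collect_relevance = TRUE)
  rep_ <- aggregate_importance(rs, top_k = 3)
  # manual accumulation from the stored records
  meta <- rs$relevance$meta
  rel <- rs$relevance$rel
  for (cl in 0:1) {
    manual <- colSums(rel[meta$true_class == cl, , drop = FALSE])
    expect_equal(unname(rep_$summed[, paste0("class", cl)]), unname(manual))
  }
  # one importance value per map block, 8 imaging maps
  expect_length(rep_$map_means, 8L)
  # top lists have the requested length and are sorted descending
  for (b in names(rep_$top)) {
    for (cl in c("class0", "class1")) {
      vals <- rep_$top[[b]][[cl]]
      expect_lte(length(vals), 3L)
      expect_true(all(diff(vals) <= 0))
    }
  }
  # pooled regions are the union of the modality's four top lists
  pooled <- rep_$pooled_regions$isc$class1
  manual_pool <- sort(unique(unlist(lapply(
    paste0("isc_", c("min", "max", "mean", "sd")),
    function(b) as.integer(sub(".*_r", "", names(rep_$top[[b]]$class1)))))))
  expect_identical(pooled, manual_pool)
  # a block with >= 10 features yields a top-10 list
  rs2 <- run_pairwise_cv(coh$labels, clinical = coh$clinical,
                         model = "nn", n_runs = 1,
                         train_cfg = train_config(iterations = 20),
                         seed = 8, collect_relevance = TRUE)
  rep2 <- aggregate_importance(rs2)
  expect_length(rep2$top$clinical$class1, min(10L, ncol(coh$clinical)))
  expect_error(aggregate_importance(
    run_pairwise_cv(coh$labels, clinical = coh$clinical, model = "svm",
                    n_runs = 1, seed = 1)), "relevance")
})

test_that("univariate table applies the right tests and Bonferroni scaling", {
  n <- 40
  kinds <- c(a = "scalar", b = "binary", c = "ordinal")
  labels <- rep(c(0L, 1L), each = n / 2)
  tab <- structure(
    data.frame(a = c(rnorm(n / 2), rnorm(n / 2)),
               b = c(rep(1L, 18), rep(0L, 2), rep(0L, 18), rep(1L, 2)),
               c = rep(3L, n),
               row.names = sprintf("s%02d", 1:n)),
    kinds = kinds, smoker_col = NA_character_,
    nicotine_col = NA_character_,
    class = c("clinical_table", "data.frame"))
  tab$a <- rep(1:20, 2)  # identical distributions across groups
  out <- univariate_table(tab, labels)
  expect_identical(out$test, c("mann-whitney", "chi-square", "mann-whitney"))
  expect_gt(out$p[1], 0.9)        # identical groups
  expect_lt(out$p[2], 0.01)       # 18/2 vs 2/18 split
  expect_true(is.na(out$p[3]))    # constant variable -> not available
  expect_equal(out$p_adj, pmin(1, out$p * 3))
})
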