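#' Draw one randomized-pair cross-validation split
#'
#' Test set: one randomly selected subject from each class. Training set:
#' every remaining subject of the smaller class plus an equal-size random
#' subset of the larger class (the surplus majority-class subjects are
#' omitted for that run, so training is always balanced and the classifier
#' is not biased toward the prevalent class).
#'
#' @param labels binary outcome vector (0/1).
#' @param seed optional integer seed for this draw.
#' @return list with `test_pos`, `test_neg` (indices of the test pair),
#'   `train` (training indices), `omitted` (majority-class indices left
#'   out).
#' @export
draw_cv_split <- function(labels, seed = NULL) {
  draw <- function() {
    pos <- which(labels == 1)
    neg <- which(labels == 0)
    if (length(pos) < 2 || length(neg) < 2)
      stop("need at least 2 subjects per class")
    test_pos <- pos[sample.int(length(pos), 1)]
    test_neg <- neg[sample.int(length(neg), 1)]
    pos_rest <- setdiff(pos, test_pos)
    neg_rest <- setdiff(neg, test_neg)
    k <- min(length(pos_rest), length(neg_rest))
    keep_pos <- if (length(pos_rest) > k)
      sort(pos_rest[sample.int(length(pos_rest), k)]) else pos_rest
    keep_neg <- if (length(neg_rest) > k)
      sort(neg_rest[sample.int(length(neg_rest), k)]) else neg_rest
    train <- sort(c(keep_pos, keep_neg))
    list(test_pos = test_pos, test_neg = test_neg, train = train,
         omitted = sort(setdiff(c(pos_rest, neg_rest), train)))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Randomized-pair cross-validation with per-run retraining
#'
#' Repeats `n_runs` times: draw a random test pair (one subject per class),
#' balance the training classes by subsampling the majority class, refit
#' the clinical preprocessor on that run's training rows only, train the
#' chosen classifier from scratch, and predict the pair. Each run's
#' accuracy is therefore 0, 50 or 100 %. Optionally records, for the
#' neural network, the layer-wise relevance of every feature for
#' predicting each test subject toward its *true* class (whether or not
#' the prediction was correct), for later importance aggregation.
#'
#' @param labels binary outcome vector.
#' @param clinical a `clinical_table`, or `NULL` if the clinical modality
#'   is not used.
#' @param imaging named list of subjects x regions feature blocks (the
#'   pooled map blocks, e.g. `vbm_min`, ..., `isc_sd`), or `NULL`.
#' @param model `"nn"` or `"svm"`.
#' @param n_runs number of randomized-pair runs (the full-scale analysis
#'   uses 2000).
#' @param train_cfg a [train_config()] (ignored for the SVM).
#' @param seed master seed; per-run seeds are derived from it.
#' @param collect_relevance record per-run LRP relevance (NN only).
#' @param fan_out first-layer fan-out of the network.
#' @return a `run_set`: list with `runs` (data.frame: run, test indices,
#'   predictions, accuracy), `layout`, `model`, `n_runs`, `seed`,
#'   `subject_ids`, and optionally `relevance` (records + matrix).
#' @export
run_pairwise_cv <- function(labels, clinical = NULL, imaging = NULL,
                            model = c("nn", "svm"), n_runs = 2000L,
                            train_cfg = train_config(), seed = 1L,
                            collect_relevance = FALSE, fan_out = 10L) {
  model <- match.arg(model)
  if (is.null(clinical) && is.null(imaging))
    stop("select at least one modality")
  n <- length(labels)
  subject_ids <- if (!is.null(clinical)) rownames(clinical)
                 else rownames(imaging[[1]])
  if (!is.null(clinical) && nrow(clinical) != n)
    stop("clinical rows do not match labels")
  if (!is.null(imaging)) {
    for (b in imaging) if (nrow(b) != n) stop("imaging rows do not match labels")
    imaging_x <- do.call(cbind, imaging)
  } else imaging_x <- NULL

  widths <- c(if (!is.null(clinical)) stats::setNames(ncol(clinical), "clinical"),
              if (!is.null(imaging)) vapply(imaging, ncol, integer(1)))
  spec <- if (model == "nn") build_network(widths, fan_out = fan_out) else NULL
  ends <- cumsum(widths)
  layout <- data.frame(block = names(widths), start = ends - widths + 1L,
                       end = ends, width = as.integer(widths),
                       row.names = NULL, stringsAsFactors = FALSE)

  # training-set size is fixed by the balancing rule; cap the mini-batch
  # size at it so small cohorts remain analysable with the default config
  n_train <- 2L * (min(sum(labels == 1), sum(labels == 0)) - 1L)
  if (train_cfg$batch_size > n_train) {
    train_cfg <- train_config(
      iterations = train_cfg$iterations, batch_size = n_train,
      learning_rate = train_cfg$learning_rate, beta1 = train_cfg$beta1,
      beta2 = train_cfg$beta2, adam_eps = train_cfg$adam_eps,
      seed = train_cfg$seed)
  }

  run_seeds <- withr::with_seed(seed,
                                sample.int(.Machine$integer.max, n_runs))
  runs <- data.frame(run = seq_len(n_runs), test_pos = NA_integer_,
                     test_neg = NA_integer_, pred_pos = NA_integer_,
                     pred_neg = NA_integer_, accuracy = NA_real_)
  rel_records <- if (collect_relevance && model == "nn") {
    list(meta = data.frame(run = integer(0), subject = integer(0),
                           true_class = integer(0)),
         rel = matrix(numeric(0), 0, sum(widths)))
  } else NULL

  for (r in seq_len(n_runs)) {
    res <- withr::with_seed(run_seeds[r], {
      split <- draw_cv_split(labels)
      test_idx <- c(split$test_pos, split$test_neg)
      if (!is.null(clinical)) {
        prep <- fit_clinical_preprocessor(clinical[split$train, ,
                                                   drop = FALSE])
        # per-run unseen-level logs are uninformative at 2000-run scale
        clin_x <- suppressMessages(apply_clinical_preprocessor(prep,
                                                               clinical))
        x <- if (is.null(imaging_x)) clin_x else cbind(clin_x, imaging_x)
      } else {
        x <- imaging_x
      }
      if (model == "nn") {
        fit <- train_network(spec, x[split$train, , drop = FALSE],
                             labels[split$train], train_cfg)
        pred <- predict_network(fit, x[test_idx, , drop = FALSE])$class
        rel <- if (collect_relevance) {
          rbind(lrp_relevance(fit, x[split$test_pos, ], target_class = 1L),
                lrp_relevance(fit, x[split$test_neg, ], target_class = 0L))
        } else NULL
      } else {
        fit <- train_svm_baseline(x[split$train, , drop = FALSE],
                                  labels[split$train])
        pred <- predict_svm(fit, x[test_idx, , drop = FALSE])
        rel <- NULL
      }
      list(split = split, pred = pred, rel = rel)
    })
    runs$test_pos[r] <- res$split$test_pos
    runs$test_neg[r] <- res$split$test_neg
    runs$pred_pos[r] <- res$pred[1]
    runs$pred_neg[r] <- res$pred[2]
    runs$accuracy[r] <- 50 * ((res$pred[1] == 1) + (res$pred[2] == 0))
    if (!is.null(rel_records) && !is.null(res$rel)) {
      rel_records$meta <- rbind(
        rel_records$meta,
        data.frame(run = c(r, r),
                   subject = c(res$split$test_pos, res$split$test_neg),
                   true_class = c(1L, 0L)))
      rel_records$rel <- rbind(rel_records$rel, res$rel)
    }
  }

  structure(list(runs = runs, layout = layout, model = model,
                 n_runs = n_runs, seed = seed, subject_ids = subject_ids,
                 relevance = rel_records),
            class = "run_set")
}
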