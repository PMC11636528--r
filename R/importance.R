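#' Aggregate layer-wise relevance into an importance report
#'
#' Sums, over all runs, each feature's relevance for predicting each test
#' subject toward its true class (relevance is recorded whether or not the
#' prediction was correct). From the per-variable sums it derives: the
#' per-class and combined sums; the mean summed importance over regions
#' for each of the eight imaging maps (a per-map contribution estimate);
#' the top-`k` features of every block per class; and, for each imaging
#' modality, the pooled set of regions that appear in the top-`k` of at
#' least one of that modality's four maps.
#'
#' @param runs a `run_set` produced with `collect_relevance = TRUE`.
#' @param top_k length of the top lists (default 10).
#' @return an `importance_report`: list with `summed` (features x
#'   2 matrix, columns `class0`/`class1`), `total` (rowSums), `map_means`,
#'   `top` (per block per class, named relevance values sorted
#'   descending), `pooled_regions` (per imaging modality per class),
#'   `layout`, `n_records`.
#' @export
aggregate_importance <- function(runs, top_k = 10L) {
  stopifnot(inherits(runs, "run_set"))
  if (is.null(runs$relevance) || nrow(runs$relevance$rel) == 0)
    stop("run set carries no relevance records (collect_relevance = TRUE needed)")
  meta <- runs$relevance$meta
  rel <- runs$relevance$rel
  layout <- runs$layout
  if (ncol(rel) != max(layout$end)) stop("relevance width does not match layout")

  summed <- vapply(c(0L, 1L), function(cl) {
    rows <- meta$true_class == cl
    if (any(rows)) colSums(rel[rows, , drop = FALSE]) else numeric(ncol(rel))
  }, numeric(ncol(rel)))
  colnames(summed) <- c("class0", "class1")
  total <- rowSums(summed)

  feature_names <- function(block) {
    row <- layout[layout$block == block, ]
    if (block == "clinical") sprintf("clinical_%03d", seq_len(row$width))
    else sprintf("%s_r%03d", block, seq_len(row$width))
  }

  imaging_blocks <- setdiff(layout$block, "clinical")
  map_means <- vapply(imaging_blocks, function(b) {
    row <- layout[layout$block == b, ]
    mean(total[row$start:row$end])
  }, numeric(1))

  top <- lapply(stats::setNames(layout$block, layout$block), function(b) {
    row <- layout[layout$block == b, ]
    idx <- row$start:row$end
    lapply(stats::setNames(c("class0", "class1"), c("class0", "class1")),
           function(cl) {
             vals <- summed[idx, cl]
             names(vals) <- feature_names(b)
             k <- min(top_k, length(vals))
             sort(vals, decreasing = TRUE)[seq_len(k)]
           })
  })

  modalities <- unique(sub("_(min|max|mean|sd)$", "", imaging_blocks))
  pooled_regions <- lapply(stats::setNames(modalities, modalities),
                           function(m) {
    maps <- grep(paste0("^", m, "_"), imaging_blocks, value = TRUE)
    lapply(stats::setNames(c("class0", "class1"), c("class0", "class1")),
           function(cl) {
             regions <- unlist(lapply(maps, function(b) {
               as.integer(sub(".*_r", "", names(top[[b]][[cl]])))
             }))
             sort(unique(regions))
           })
  })

  structure(list(summed = summed, total = total, map_means = map_means,
                 top = top, pooled_regions = pooled_regions,
                 layout = layout, n_records = nrow(meta)),
            class = "importance_report")
}

#' Univariate group-difference table for the clinical variables
#'
#' For every clinical variable, tests the group difference with a
#' Mann-Whitney U-test (scalar and ordinal variables) or a Pearson
#' chi-square test (binary and categorical variables), and adjusts the
#' p-values for multiple comparisons with the Bonferroni correction
#' (`p_adj = min(1, p * n_variables)`). Variables that are constant (or
#' entirely missing) in the pooled sample get `NA` p-values.
#'
#' @param clinical a `clinical_table`.
#' @param labels binary outcome vector.
#' @return data.frame with `variable`, `kind`, `test`, `statistic`, `p`,
#'   `p_adj`.
#' @export
univariate_table <- function(clinical, labels) {
  stopifnot(inherits(clinical, "clinical_table"))
  if (length(unique(labels[!is.na(labels)])) < 2)
    stop("need subjects in both groups")
  kinds <- attr(clinical, "kinds")
  g <- factor(labels, levels = c(0, 1))
  res <- lapply(colnames(clinical), function(j) {
    kind <- kinds[[j]]
    x <- clinical[[j]]
    ok <- !is.na(x)
    row <- data.frame(variable = j, kind = kind,
                      test = if (kind %in% c("scalar", "ordinal"))
                        "mann-whitney" else "chi-square",
                      statistic = NA_real_, p = NA_real_,
                      stringsAsFactors = FALSE)
    xx <- x[ok]; gg <- g[ok]
    if (length(unique(xx)) < 2 || length(unique(gg)) < 2) return(row)
    if (kind %in% c("scalar", "ordinal")) {
      wt <- suppressWarnings(stats::wilcox.test(as.numeric(xx) ~ gg,
                                                exact = FALSE))
      row$statistic <- unname(wt$statistic)
      row$p <- wt$p.value
    } else {
      ct <- suppressWarnings(stats::chisq.test(table(xx, gg)))
      row$statistic <- unname(ct$statistic)
      row$p <- ct$p.value
    }
    row
  })
  out <- do.call(rbind, res)
  out$p_adj <- pmin(1, out$p * ncol(clinical))
  out
}
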