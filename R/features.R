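#' Region-wise pooling of a voxel map
#'
#' Reduces a voxel map to four per-region statistics -- minimum, maximum,
#' mean, and standard deviation (sample SD, n-1 denominator) of the voxels
#' in each atlas region.
#'
#' @param map numeric array or vector of voxel values.
#' @param atlas integer label volume on the same grid (labels 1..R; 0 =
#'   background, excluded).
#' @param n_regions number of regions; defaults to `max(atlas)`.
#' @return numeric matrix R x 4 with columns `min`, `max`, `mean`, `sd` and
#'   rows indexed by atlas label.
#' @export
pool_map <- function(map, atlas, n_regions = NULL) {
  map <- as.vector(map)
  lab <- as.vector(atlas)
  if (length(map) != length(lab)) stop("map and atlas grids differ")
  if (is.null(n_regions)) n_regions <- max(lab)
  out <- matrix(NA_real_, n_regions, 4,
                dimnames = list(NULL, c("min", "max", "mean", "sd")))
  keep <- lab >= 1L
  groups <- split(map[keep], lab[keep])
  for (r in seq_len(n_regions)) {
    vals <- groups[[as.character(r)]]
    if (is.null(vals) || length(vals) == 0)
      stop(sprintf("atlas label %d has no voxels", r))
    out[r, ] <- c(min(vals), max(vals), mean(vals),
                  if (length(vals) > 1) stats::sd(vals) else 0)
  }
  out
}

#' Pool a stack of per-subject voxel maps into four region-feature blocks
#'
#' Applies [pool_map()] to every row of a subjects x voxels matrix and
#' returns the four pooled blocks (`<prefix>_min`, `<prefix>_max`,
#' `<prefix>_mean`, `<prefix>_sd`), each a subjects x regions matrix.
#'
#' @param maps subjects x voxels matrix (rownames = subject ids).
#' @param atlas integer label volume.
#' @param prefix block-name prefix, e.g. `"vbm"` or `"isc"`.
#' @param n_regions number of regions; defaults to `max(atlas)`.
#' @return named list of four subjects x regions matrices.
#' @export
pool_subject_maps <- function(maps, atlas, prefix, n_regions = NULL) {
  lab <- as.vector(atlas)
  if (is.null(n_regions)) n_regions <- max(lab)
  stats_names <- c("min", "max", "mean", "sd")
  blocks <- lapply(stats_names, function(s)
    matrix(NA_real_, nrow(maps), n_regions,
           dimnames = list(rownames(maps),
                           sprintf("%s_%s_r%03d", prefix, s,
                                   seq_len(n_regions)))))
  names(blocks) <- paste(prefix, stats_names, sep = "_")
  for (i in seq_len(nrow(maps))) {
    pooled <- pool_map(maps[i, ], atlas, n_regions)
    for (k in seq_along(stats_names))
      blocks[[k]][i, ] <- pooled[, stats_names[k]]
  }
  blocks
}

#' Assemble a stacked multimodal feature set
#'
#' Stacks the selected modality blocks -- the (preprocessed) clinical
#' matrix and/or the four pooled grey-matter (VBM) and four pooled ISC
#' blocks -- into one feature matrix per subject, and records the modality
#' layout (which column range belongs to which block). Imaging features are
#' passed through unscaled: both ISC z values and grey-matter
#' concentrations are naturally order-1 quantities, and only the clinical
#' variables are min-max normalized (by the clinical preprocessor).
#'
#' @param clinical numeric matrix from [apply_clinical_preprocessor()], or
#'   `NULL`.
#' @param vbm,isc named lists of four subjects x regions matrices
#'   (`*_min`, `*_max`, `*_mean`, `*_sd`, e.g. from `pool_subject_maps`),
#'   or `NULL`.
#' @param selection character subset of `c("clinical", "vbm", "isc")`.
#' @param labels optional binary outcome vector stored alongside.
#' @return a `feature_set`: list with `x` (subjects x features matrix),
#'   `layout` (data.frame with `block`, `start`, `end`, `width`),
#'   `subject_ids`, `labels`.
#' @export
assemble_feature_set <- function(clinical = NULL, vbm = NULL, isc = NULL,
                                 selection = c("clinical", "vbm", "isc"),
                                 labels = NULL) {
  if (length(selection) == 0) stop("empty modality selection")
  selection <- match.arg(selection, c("clinical", "vbm", "isc"),
                         several.ok = TRUE)
  blocks <- list()
  if ("clinical" %in% selection) {
    if (is.null(clinical)) stop("clinical selected but not supplied")
    blocks$clinical <- as.matrix(clinical)
  }
  if ("vbm" %in% selection) {
    if (is.null(vbm)) stop("vbm selected but not supplied")
    blocks <- c(blocks, vbm)
  }
  if ("isc" %in% selection) {
    if (is.null(isc)) stop("isc selected but not supplied")
    blocks <- c(blocks, isc)
  }
  ids <- rownames(blocks[[1]])
  for (b in blocks) {
    if (!identical(rownames(b), ids))
      stop("subject ids differ across modality blocks")
  }
  x <- do.call(cbind, blocks)
  widths <- vapply(blocks, ncol, integer(1))
  ends <- cumsum(widths)
  layout <- data.frame(block = names(blocks),
                       start = ends - widths + 1L, end = ends,
                       width = widths, row.names = NULL,
                       stringsAsFactors = FALSE)
  structure(list(x = x, layout = layout, subject_ids = ids,
                 labels = labels),
            class = "feature_set")
}

#' Map a feature column index to its block and within-block position
#'
#' Inverse of the layout: returns, for each feature index, the block name
#' and the position inside that block (region number for imaging blocks,
#' variable number for the clinical block).
#'
#' @param layout the `layout` data.frame of a `feature_set`.
#' @param index integer vector of feature column indices.
#' @return data.frame with `index`, `block`, `position`.
#' @export
feature_location <- function(layout, index) {
  block_idx <- findInterval(index, layout$start)
  if (any(index < 1 | index > max(layout$end)))
    stop("feature index out of range")
  data.frame(index = index, block = layout$block[block_idx],
             position = index - layout$start[block_idx] + 1L,
             stringsAsFactors = FALSE)
}
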