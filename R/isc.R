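#' Fisher z-transform of a correlation coefficient
#'
#' `atanh(r)`, the variance-stabilizing transform applied to Pearson
#' correlations before averaging. Correlations are first clamped to
#' `|r| <= 1 - eps` so that numerically perfect correlations (identical
#' time courses) do not produce infinities.
#'
#' @param r numeric vector of correlations.
#' @param eps clamping margin (default `1e-7`).
#' @return numeric vector of z values.
#' @export
#' @examples
#' fisher_z(0.8)  # 0.5 * log(1.8 / 0.2) = 1.0986...
fisher_z <- function(r, eps = 1e-7) {
  if (!is.numeric(r)) stop("fisher_z expects numeric input")
  atanh(pmin(1 - eps, pmax(-(1 - eps), r)))
}

# column-standardize a time x voxel matrix; zero-variance columns become
# all-zero so any correlation involving them is 0
standardize_ts <- function(ts) {
  tt <- nrow(ts)
  mu <- colMeans(ts)
  xc <- sweep(ts, 2, mu)
  sd <- sqrt(colSums(xc^2) / (tt - 1))
  flat <- sd <= 0 | !is.finite(sd)
  sd[flat] <- 1
  z <- sweep(xc, 2, sd, "/")
  if (any(flat)) z[, flat] <- 0
  list(z = z, flat = flat)
}

#' Per-subject inter-subject correlation map against a reference group
#'
#' For every voxel, computes the Pearson correlation of the subject's time
#' course with each reference subject's time course at that voxel, Fisher
#' z-transforms each correlation, and averages the z values over the
#' reference group. The map stays in z space (it is never transformed back
#' to r). Only subject-versus-reference pairs enter the average; pairs
#' within the reference group are not computed.
#'
#' Voxels where either time course has zero variance get correlation 0
#' (they carry no signal; typically masked-edge voxels). A message reports
#' how many such voxels were encountered.
#'
#' @param subject_ts time x voxel matrix for the subject.
#' @param reference_ts list of time x voxel matrices, one per reference
#'   subject, all on the same grid and time length.
#' @param grid_shape optional integer vector; if given, the z map is
#'   returned as an array of this shape.
#' @param subject_id optional identifier stored in the result.
#' @param eps clamping margin passed to [fisher_z()].
#' @return an `isc_map`: list with `z` (mean Fisher-z per voxel, vector or
#'   array), `n_reference`, `subject_id`, `grid_shape`.
#' @export
compute_isc_map <- function(subject_ts, reference_ts, grid_shape = NULL,
                            subject_id = NULL, eps = 1e-7) {
  if (!is.list(reference_ts) || length(reference_ts) < 1)
    stop("need at least one reference subject")
  tt <- nrow(subject_ts)
  v <- ncol(subject_ts)
  for (ref in reference_ts) {
    if (nrow(ref) != tt) stop("time length differs between subject and reference")
    if (ncol(ref) != v) stop("voxel count differs between subject and reference")
  }
  if (tt < 3) stop("need at least 3 timepoints")

  zs <- standardize_ts(subject_ts)
  acc <- numeric(v)
  n_flat <- sum(zs$flat)
  for (ref in reference_ts) {
    zr <- standardize_ts(ref)
    r <- colSums(zs$z * zr$z) / (tt - 1)
    acc <- acc + fisher_z(r, eps = eps)
    n_flat <- n_flat + sum(zr$flat & !zs$flat)
  }
  zbar <- acc / length(reference_ts)
  if (n_flat > 0)
    message(sprintf("compute_isc_map: %d zero-variance voxel time courses; correlation set to 0",
                    n_flat))
  if (!is.null(grid_shape)) {
    stopifnot(prod(grid_shape) == v)
    dim(zbar) <- grid_shape
  }
  structure(list(z = zbar, n_reference = length(reference_ts),
                 subject_id = subject_id, grid_shape = grid_shape),
            class = "isc_map")
}

#' ISC maps for every subject in a cohort bundle
#'
#' @param cohort a `cohort_bundle`.
#' @return matrix (subjects x voxels) of mean Fisher-z values.
#' @export
compute_cohort_isc <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_bundle"))
  vols <- cohort$volumes
  maps <- t(vapply(vols$subject_ts, function(ts) {
    as.vector(compute_isc_map(ts, vols$reference_ts)$z)
  }, numeric(prod(vols$grid_shape))))
  rownames(maps) <- cohort$subject_ids
  maps
}
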