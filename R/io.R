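#' Save a cohort bundle to a directory
#'
#' Writes the atlas and grey-matter volumes and every fMRI time series as
#' NIfTI (`.nii.gz`; time series as 4D volumes with time in the fourth
#' dimension), the clinical table and outcome labels as CSV with a YAML
#' sidecar declaring each column's kind and the special-rule columns, and
#' a JSON manifest carrying the configuration and an MD5 checksum of every
#' file. [load_cohort()] verifies the checksums and reproduces the bundle
#' exactly (integer volumes bit-exact; floats stored as float64).
#'
#' @param cohort a `cohort_bundle`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
save_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- cohort$config$grid_shape
  vols <- cohort$volumes

  write_vol <- function(x, file, datatype) {
    RNifti::writeNifti(RNifti::asNifti(x, datatype = datatype),
                       file.path(dir, file))
    file
  }
  files <- character(0)
  files <- c(files, write_vol(vols$atlas, "atlas.nii.gz", "int32"))
  vbm4d <- array(t(vols$vbm), dim = c(grid, nrow(vols$vbm)))
  files <- c(files, write_vol(vbm4d, "vbm.nii.gz", "double"))
  for (i in seq_along(vols$subject_ts)) {
    arr <- array(t(vols$subject_ts[[i]]),
                 dim = c(grid, nrow(vols$subject_ts[[i]])))
    files <- c(files, write_vol(arr, sprintf("func_sub%03d.nii.gz", i),
                                "double"))
  }
  for (i in seq_along(vols$reference_ts)) {
    arr <- array(t(vols$reference_ts[[i]]),
                 dim = c(grid, nrow(vols$reference_ts[[i]])))
    files <- c(files, write_vol(arr, sprintf("func_ref%03d.nii.gz", i),
                                "double"))
  }

  clin <- as.data.frame(cohort$clinical)
  utils::write.csv(cbind(subject_id = rownames(clin), clin),
                   file.path(dir, "clinical.csv"), row.names = FALSE)
  files <- c(files, "clinical.csv")
  mask <- attr(cohort$clinical, "missing_mask")
  utils::write.csv(cbind(subject_id = rownames(mask),
                         as.data.frame(mask)),
                   file.path(dir, "clinical_missing.csv"),
                   row.names = FALSE)
  files <- c(files, "clinical_missing.csv")
  yaml::write_yaml(list(kinds = as.list(attr(cohort$clinical, "kinds")),
                        smoker_col = attr(cohort$clinical, "smoker_col"),
                        nicotine_col = attr(cohort$clinical, "nicotine_col")),
                   file.path(dir, "clinical_meta.yaml"))
  files <- c(files, "clinical_meta.yaml")
  utils::write.csv(data.frame(subject_id = cohort$subject_ids,
                              label = cohort$labels),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  files <- c(files, "labels.csv")

  checksums <- as.list(tools::md5sum(file.path(dir, files)))
  names(checksums) <- files
  manifest <- list(format_version = 1L,
                   config = unclass(cohort$config),
                   n_subject_ts = length(vols$subject_ts),
                   n_reference_ts = length(vols$reference_ts),
                   files = checksums)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a cohort bundle saved with [save_cohort()]
#'
#' @param dir directory containing `manifest.json`.
#' @param verify_checksums refuse to load when any file's MD5 differs from
#'   the manifest (default `TRUE`).
#' @return a `cohort_bundle`.
#' @export
load_cohort <- function(dir, verify_checksums = TRUE) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path))
    stop(sprintf("no manifest.json in '%s': not a cohort directory", dir))
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (is.null(manifest$format_version) || manifest$format_version != 1L)
    stop("unsupported or missing cohort format version")
  if (verify_checksums) {
    for (f in names(manifest$files)) {
      path <- file.path(dir, f)
      if (!file.exists(path)) stop(sprintf("missing file '%s'", f))
      actual <- unname(tools::md5sum(path))
      if (!identical(actual, manifest$files[[f]]))
        stop(sprintf("checksum mismatch for '%s': file corrupt or tampered", f))
    }
  }
  cfgl <- manifest$config
  config <- cohort_config(
    n_subjects = cfgl$n_subjects, n_positive = cfgl$n_positive,
    n_reference = cfgl$n_reference, n_clinical = cfgl$n_clinical,
    grid_shape = cfgl$grid_shape, n_regions = cfgl$n_regions,
    n_timepoints = cfgl$n_timepoints,
    clinical_effect_sizes = cfgl$clinical_effect_sizes,
    isc_attenuation = cfgl$isc_attenuation, vbm_effects = cfgl$vbm_effects,
    missing_fraction = cfgl$missing_fraction,
    n_missing_vars = cfgl$n_missing_vars, noise_sd = cfgl$noise_sd,
    vbm_noise_sd = cfgl$vbm_noise_sd, seed = cfgl$seed)
  grid <- config$grid_shape
  v <- prod(grid)

  read_vol <- function(file) {
    arr <- RNifti::readNifti(file.path(dir, file))
    array(as.vector(arr), dim = dim(arr))
  }
  atlas <- read_vol("atlas.nii.gz")
  storage.mode(atlas) <- "integer"
  vbm4d <- read_vol("vbm.nii.gz")
  n_sub <- dim(vbm4d)[4]
  vbm <- t(matrix(vbm4d, nrow = v))
  read_ts <- function(file) {
    arr <- read_vol(file)
    t(matrix(arr, nrow = v))  # time x voxels
  }
  subject_ts <- lapply(seq_len(manifest$n_subject_ts), function(i)
    read_ts(sprintf("func_sub%03d.nii.gz", i)))
  reference_ts <- lapply(seq_len(manifest$n_reference_ts), function(i)
    read_ts(sprintf("func_ref%03d.nii.gz", i)))

  clin_raw <- utils::read.csv(file.path(dir, "clinical.csv"),
                              stringsAsFactors = FALSE)
  ids <- clin_raw$subject_id
  clin <- clin_raw[, -1, drop = FALSE]
  rownames(clin) <- ids
  meta <- yaml::read_yaml(file.path(dir, "clinical_meta.yaml"))
  kinds <- unlist(meta$kinds)
  for (j in names(kinds)) {
    if (kinds[[j]] == "categorical" && !is.factor(clin[[j]])) {
      lev <- sort(unique(stats::na.omit(clin[[j]])))
      clin[[j]] <- factor(clin[[j]], levels = lev)
    } else if (kinds[[j]] %in% c("ordinal", "binary")) {
      clin[[j]] <- as.integer(clin[[j]])
    }
  }
  mask_raw <- utils::read.csv(file.path(dir, "clinical_missing.csv"))
  mask <- as.matrix(mask_raw[, -1, drop = FALSE]) == TRUE
  rownames(mask) <- mask_raw$subject_id
  clinical <- structure(clin, kinds = kinds, missing_mask = mask,
                        smoker_col = meta$smoker_col,
                        nicotine_col = meta$nicotine_col,
                        class = c("clinical_table", "data.frame"))
  labels_df <- utils::read.csv(file.path(dir, "labels.csv"))
  labels <- as.integer(labels_df$label)

  vbm <- vbm[seq_len(n_sub), , drop = FALSE]
  rownames(vbm) <- labels_df$subject_id
  names(subject_ts) <- labels_df$subject_id
  names(reference_ts) <- sprintf("ref%03d", seq_along(reference_ts))
  volumes <- structure(list(atlas = atlas, vbm = vbm,
                            subject_ts = subject_ts,
                            reference_ts = reference_ts, labels = labels,
                            grid_shape = grid),
                       class = "volume_bundle")
  structure(list(config = config, labels = labels,
                 subject_ids = labels_df$subject_id, clinical = clinical,
                 volumes = volumes),
            class = "cohort_bundle")
}

#' Save an analysis report to a directory
#'
#' Writes the report's scalar results (accuracies, confidence interval,
#' confusion counts and metrics, p-values) and the resolved analysis
#' configuration to `report.json`, the per-run records to `runs.csv`, the
#' univariate table (if present) to `univariate.csv`, and the importance
#' sums (if present) to `importance.csv`.
#'
#' @param report a `trs_report` from [run_analysis()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
save_report <- function(report, dir) {
  stopifnot(inherits(report, "trs_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scalar <- list(
    model = report$model, modalities = report$modalities,
    mean_accuracy = report$mean_accuracy$mean,
    ci_lower = report$mean_accuracy$ci[1],
    ci_upper = report$mean_accuracy$ci[2],
    voted_confusion = as.list(report$voted$confusion),
    metrics = as.list(report$metrics),
    permutation_p = report$permutation$p.value,
    n_runs = report$config$n_runs, n_perm = report$config$n_perm,
    config = report$config)
  jsonlite::write_json(scalar, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(report$runs$runs, file.path(dir, "runs.csv"),
                   row.names = FALSE)
  if (!is.null(report$univariate))
    utils::write.csv(report$univariate, file.path(dir, "univariate.csv"),
                     row.names = FALSE)
  if (!is.null(report$importance))
    utils::write.csv(
      data.frame(feature = seq_len(nrow(report$importance$summed)),
                 report$importance$summed,
                 total = report$importance$total),
      file.path(dir, "importance.csv"), row.names = FALSE)
  invisible(dir)
}
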