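#' Configuration for a synthetic first-episode-psychosis cohort
#'
#' Bundles every knob of the synthetic-data generator. The defaults mirror
#' the study design the analysis machinery assumes: 38 subjects of whom 7
#' are in the positive (clozapine-indicated, treatment-resistant) class, an
#' independent reference group of 44 for inter-subject correlation, 81
#' mixed-type clinical variables with about 4.2 % of values missing spread
#' over 27 of them, and two imaging modalities (grey-matter concentration
#' and naturalistic-fMRI time series) on a common voxel grid with an
#' integer-labelled parcellation.
#'
#' Planted group effects are configurable per variable/region:
#' `clinical_effect_sizes` are standardized mean shifts added to positive
#' subjects' clinical variables; `isc_attenuation` multiplies the positive
#' subjects' coupling to the shared stimulus-driven signal (1 = no effect,
#' 0 = fully decoupled, so their expected inter-subject correlation in that
#' region drops); `vbm_effects` shift the positive subjects' regional
#' grey-matter level. Setting all three to "no effect" yields a null cohort
#' in which every downstream group test is calibrated at chance.
#'
#' The default effect pattern plants a moderate clinical signal on four
#' variables (about one pooled SD, mixed signs, mimicking the kind of
#' symptom/functioning differences seen in early-psychosis cohorts), halves
#' the shared-signal coupling in the first quarter of the regions, and
#' lowers grey matter by one noise SD in the first three regions.
#'
#' @param n_subjects number of cohort subjects.
#' @param n_positive number of positive-class subjects (must be < n_subjects).
#' @param n_reference number of reference-group subjects (ISC only).
#' @param n_clinical number of clinical variables.
#' @param grid_shape integer vector of length 3, the voxel grid.
#' @param n_regions number of atlas regions (use 274 for full-scale
#'   emulation of a whole-brain parcellation; the default 20 keeps the
#'   object desk-sized).
#' @param n_timepoints fMRI time-series length.
#' @param clinical_effect_sizes numeric vector (recycled with zeros to
#'   `n_clinical`) of standardized group mean shifts; `NULL` for the default
#'   pattern.
#' @param isc_attenuation numeric vector in \[0,1\] per region; `NULL` for the
#'   default pattern.
#' @param vbm_effects numeric vector per region; `NULL` for the default
#'   pattern.
#' @param missing_fraction overall fraction of clinical cells made missing.
#' @param n_missing_vars number of clinical columns that carry the
#'   missingness.
#' @param noise_sd white-noise SD added to every voxel time course
#'   (the shared latent signal has SD 1, so coupling 1 gives an expected
#'   subject-reference correlation of 1/(1+noise_sd^2)).
#' @param vbm_noise_sd voxel noise SD of the grey-matter volumes.
#' @param seed integer seed; the whole bundle is a deterministic function of
#'   the configuration including this seed.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 38, n_positive = 7, n_reference = 44,
                          n_clinical = 81, grid_shape = c(12, 12, 12),
                          n_regions = 20, n_timepoints = 240,
                          clinical_effect_sizes = NULL,
                          isc_attenuation = NULL, vbm_effects = NULL,
                          missing_fraction = 0.042, n_missing_vars = 27,
                          noise_sd = 1, vbm_noise_sd = 0.05, seed = 1L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1))
  counts <- c(n_subjects, n_positive, n_reference, n_clinical, n_regions,
              n_timepoints)
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (n_positive >= n_subjects) stop("n_positive must be < n_subjects")
  if (missing_fraction < 0 || missing_fraction >= 1)
    stop("missing_fraction must be in [0, 1)")

  if (is.null(clinical_effect_sizes)) {
    clinical_effect_sizes <- numeric(n_clinical)
    planted <- c(5L, 9L, 13L, 17L)
    planted <- planted[planted <= n_clinical]
    clinical_effect_sizes[planted] <- c(1, -1, 1, -0.8)[seq_along(planted)]
  }
  if (length(clinical_effect_sizes) > n_clinical)
    stop("clinical_effect_sizes longer than n_clinical")
  clinical_effect_sizes <-
    c(clinical_effect_sizes,
      numeric(n_clinical - length(clinical_effect_sizes)))

  if (is.null(isc_attenuation)) {
    isc_attenuation <- rep(1, n_regions)
    isc_attenuation[seq_len(max(1L, n_regions %/% 4L))] <- 0.5
  }
  if (length(isc_attenuation) != n_regions)
    stop("isc_attenuation must have one entry per region")
  if (any(isc_attenuation < 0 | isc_attenuation > 1))
    stop("isc_attenuation entries must lie in [0, 1]")

  if (is.null(vbm_effects)) {
    vbm_effects <- numeric(n_regions)
    vbm_effects[seq_len(min(3L, n_regions))] <- -vbm_noise_sd
  }
  if (length(vbm_effects) != n_regions)
    stop("vbm_effects must have one entry per region")

  if (n_missing_vars > max(0L, n_clinical - 2L))
    stop("n_missing_vars exceeds the number of eligible clinical columns")

  structure(list(
    n_subjects = as.integer(n_subjects),
    n_positive = as.integer(n_positive),
    n_reference = as.integer(n_reference),
    n_clinical = as.integer(n_clinical),
    grid_shape = as.integer(grid_shape),
    n_regions = as.integer(n_regions),
    n_timepoints = as.integer(n_timepoints),
    clinical_effect_sizes = as.numeric(clinical_effect_sizes),
    isc_attenuation = as.numeric(isc_attenuation),
    vbm_effects = as.numeric(vbm_effects),
    missing_fraction = missing_fraction,
    n_missing_vars = as.integer(n_missing_vars),
    noise_sd = noise_sd,
    vbm_noise_sd = vbm_noise_sd,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' A null configuration: no planted group effect anywhere
#'
#' Convenience wrapper around [cohort_config()] with all clinical effect
#' sizes zero, no ISC attenuation and no grey-matter shift, so that every
#' downstream feature has the same distribution in both classes.
#'
#' @param ... passed to [cohort_config()].
#' @return a `cohort_config`.
#' @export
null_cohort_config <- function(...) {
  cfg <- cohort_config(...)
  cfg$clinical_effect_sizes <- numeric(cfg$n_clinical)
  cfg$isc_attenuation <- rep(1, cfg$n_regions)
  cfg$vbm_effects <- numeric(cfg$n_regions)
  cfg
}

# kind of each clinical column; columns 1-2 are the smoking pair that
# exercises the conditional imputation rule, the rest cycle through a fixed
# mixed-type pattern (1/3 scalar, 1/3 ordinal, 1/6 binary, 1/6 categorical)
clinical_kinds <- function(n_clinical) {
  pattern <- c("scalar", "scalar", "ordinal", "ordinal", "binary",
               "categorical")
  kinds <- c("binary", "scalar",
             pattern[((seq_len(max(0L, n_clinical - 2L)) - 1L) %%
                        length(pattern)) + 1L])
  kinds <- kinds[seq_len(n_clinical)]
  names(kinds) <- clinical_names(n_clinical)
  kinds
}

clinical_names <- function(n_clinical) {
  nm <- sprintf("clin%03d", seq_len(n_clinical))
  if (n_clinical >= 1) nm[1] <- "smoker"
  if (n_clinical >= 2) nm[2] <- "nicotine_dep"
  nm
}

#' Generate a toy integer-labelled parcellation
#'
#' Tiles the voxel grid with `n_regions` contiguous blocks labelled
#' `1..R` (label 0 is reserved for background and unused here: the whole
#' grid is in-mask). Block sizes differ by at most one voxel. The result is
#' a deterministic function of the configuration (no randomness).
#'
#' @param config a [cohort_config()].
#' @return integer array with `dim = config$grid_shape`.
#' @export
generate_atlas <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  v <- prod(config$grid_shape)
  r <- config$n_regions
  if (v < 2L * r)
    stop(sprintf("grid with %d voxels too small for %d regions (need >= 2 voxels per region)",
                 v, r))
  sizes <- rep(v %/% r, r)
  extra <- v %% r
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  labels <- rep.int(seq_len(r), sizes)
  array(as.integer(labels), dim = config$grid_shape)
}

#' Generate a mixed-type clinical table with planted group effects
#'
#' Produces `n_clinical` columns of scalar, ordinal, binary and categorical
#' variables. Positive-class subjects receive the standardized mean shifts
#' in `config$clinical_effect_sizes` (applied on the latent scale for
#' ordinal/binary/categorical variables). Missing values are planted
#' completely at random within exactly `n_missing_vars` designated columns
#' so that the overall missing fraction matches `missing_fraction`.
#'
#' Two columns carry a special structure: a binary `smoker` flag and a
#' nicotine-dependence score that is only defined for smokers (absent --
#' `NA` -- for non-smokers). The conditional absence is structural, not
#' random missingness, and is excluded from the planted missing mask; it
#' exists to exercise the conditional imputation rule of the clinical
#' preprocessor.
#'
#' @param config a [cohort_config()].
#' @param labels binary outcome vector of length `n_subjects`.
#' @return a `clinical_table`: a data.frame with attributes `kinds`
#'   (named character vector), `missing_mask` (logical matrix of planted
#'   missingness), `smoker_col` and `nicotine_col`.
#' @export
generate_clinical <- function(config, labels) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  if (length(labels) != n) stop("labels length must equal n_subjects")
  p <- config$n_clinical
  kinds <- clinical_kinds(p)
  eff <- config$clinical_effect_sizes
  cols <- vector("list", p)
  names(cols) <- names(kinds)

  smoker <- stats::rbinom(n, 1, stats::plogis(stats::qlogis(0.3) +
                                                1.7 * eff[1] * labels))
  for (j in seq_len(p)) {
    e <- eff[j]
    cols[[j]] <- switch(
      kinds[j],
      scalar = stats::rnorm(n) + e * labels,
      ordinal = {
        latent <- stats::rnorm(n) + e * labels
        as.integer(pmin(6, pmax(0, round(1.5 * latent + 3))))
      },
      binary = stats::rbinom(n, 1, stats::plogis(stats::qlogis(0.35) +
                                                   1.7 * e * labels)),
      categorical = {
        nl <- 4L + (j %% 3L)  # 4..6 levels
        logits <- matrix(0, n, nl)
        logits[, nl] <- e * labels
        pr <- exp(logits) / rowSums(exp(logits))
        lev <- paste0("lvl", seq_len(nl))
        factor(lev[apply(pr, 1, function(q) sample.int(nl, 1, prob = q))],
               levels = lev)
      })
  }
  if (p >= 1) cols[[1]] <- smoker
  if (p >= 2) {
    nic <- pmin(10, pmax(0, round(stats::rnorm(n, 3 + 2 * eff[2] * labels,
                                               2))))
    nic[smoker == 0] <- NA_integer_
    cols[[2]] <- as.integer(nic)
  }
  tab <- as.data.frame(cols, stringsAsFactors = FALSE)
  rownames(tab) <- sprintf("sub%03d", seq_len(n))

  mask <- matrix(FALSE, n, p, dimnames = list(rownames(tab), names(kinds)))
  if (config$missing_fraction > 0 && config$n_missing_vars > 0) {
    eligible <- setdiff(seq_len(p), c(1L, 2L))
    miss_cols <- sort(sample(eligible, config$n_missing_vars))
    m_total <- max(config$n_missing_vars,
                   round(config$missing_fraction * n * p))
    cap <- max(1L, n - 2L)  # keep >= 2 observed values per column
    m_total <- min(m_total, length(miss_cols) * cap)
    cells <- expand.grid(row = seq_len(n), col = miss_cols)
    # one guaranteed cell per designated column, then the rest at random
    first <- vapply(miss_cols, function(cc) {
      which(cells$col == cc)[sample.int(n, 1)]
    }, integer(1))
    remaining <- setdiff(seq_len(nrow(cells)), first)
    extra <- sample(remaining, m_total - length(first))
    chosen <- cells[c(first, extra), ]
    # enforce the per-column cap (drop surplus cells, rare at defaults)
    keep <- unlist(lapply(split(seq_len(nrow(chosen)), chosen$col),
                          function(ii) ii[seq_len(min(length(ii), cap))]),
                   use.names = FALSE)
    chosen <- chosen[keep, ]
    for (i in seq_len(nrow(chosen))) {
      tab[chosen$row[i], chosen$col[i]] <- NA
      mask[chosen$row[i], chosen$col[i]] <- TRUE
    }
  }

  structure(tab, kinds = kinds, missing_mask = mask,
            smoker_col = if (p >= 1) "smoker" else NA_character_,
            nicotine_col = if (p >= 2) "nicotine_dep" else NA_character_,
            class = c("clinical_table", "data.frame"))
}

#' Generate synthetic imaging data with inter-subject correlation structure
#'
#' Each atlas region has one shared latent "stimulus" signal (standard
#' Gaussian white noise over time) drawn once per cohort -- the same movie
#' drives everyone. A subject's voxel time course in region r is
#' `coupling * signal_r + noise`, where reference subjects always have
#' coupling 1 and positive-class cohort subjects have their coupling
#' multiplied by `isc_attenuation[r]`, so their expected correlation with
#' the reference group is reduced there. Grey-matter volumes are a regional
#' base level (uniform in 0.35--0.65, drawn once per cohort) plus
#' `vbm_effects[r]` for positive subjects plus voxel noise.
#'
#' @param config a [cohort_config()].
#' @param labels binary outcome vector of length `n_subjects`.
#' @param atlas integer label volume from [generate_atlas()].
#' @return a `volume_bundle`: list with `atlas`, `vbm` (subjects x voxels
#'   matrix), `subject_ts` and `reference_ts` (lists of time x voxels
#'   matrices), `labels`, and `grid_shape`.
#' @export
generate_imaging <- function(config, labels, atlas) {
  stopifnot(inherits(config, "cohort_config"))
  if (length(labels) != config$n_subjects)
    stop("labels length must equal n_subjects")
  if (!identical(dim(atlas), config$grid_shape) &&
      !identical(as.integer(dim(atlas)), config$grid_shape))
    stop("atlas grid does not match config$grid_shape")
  v <- prod(config$grid_shape)
  tt <- config$n_timepoints
  r <- config$n_regions
  vox_region <- as.vector(atlas)
  if (!setequal(unique(vox_region), seq_len(r)))
    stop("atlas labels do not cover 1..n_regions")

  signal <- matrix(stats::rnorm(tt * r), tt, r)  # shared latent per region
  base <- stats::runif(r, 0.35, 0.65)

  make_ts <- function(coupling) {
    signal[, vox_region, drop = FALSE] *
      rep(coupling[vox_region], each = tt) +
      matrix(stats::rnorm(tt * v, sd = config$noise_sd), tt, v)
  }
  subject_ts <- lapply(seq_len(config$n_subjects), function(i) {
    coupling <- if (labels[i] == 1) config$isc_attenuation else rep(1, r)
    make_ts(coupling)
  })
  reference_ts <- lapply(seq_len(config$n_reference), function(i) {
    make_ts(rep(1, r))
  })
  vbm <- t(vapply(seq_len(config$n_subjects), function(i) {
    base[vox_region] + labels[i] * config$vbm_effects[vox_region] +
      stats::rnorm(v, sd = config$vbm_noise_sd)
  }, numeric(v)))
  rownames(vbm) <- sprintf("sub%03d", seq_len(config$n_subjects))
  names(subject_ts) <- rownames(vbm)
  names(reference_ts) <- sprintf("ref%03d", seq_len(config$n_reference))

  structure(list(atlas = atlas, vbm = vbm, subject_ts = subject_ts,
                 reference_ts = reference_ts, labels = labels,
                 grid_shape = config$grid_shape),
            class = "volume_bundle")
}

#' Generate a complete synthetic cohort
#'
#' Draws outcome labels (`n_positive` positives at random positions), the
#' parcellation, the clinical table and the imaging bundle, all from
#' `config$seed`. Identical configurations produce identical bundles.
#'
#' @param config a [cohort_config()].
#' @return a `cohort_bundle`: list with `config`, `labels`, `subject_ids`,
#'   `clinical` (a `clinical_table`), and `volumes` (a `volume_bundle`).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, {
    labels <- integer(config$n_subjects)
    labels[sample.int(config$n_subjects, config$n_positive)] <- 1L
    atlas <- generate_atlas(config)
    clinical <- generate_clinical(config, labels)
    volumes <- generate_imaging(config, labels, atlas)
  })
  structure(list(config = config, labels = labels,
                 subject_ids = rownames(clinical),
                 clinical = clinical, volumes = volumes),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d subjects (%d positive), %d reference, %d clinical variables\n",
    x$config$n_subjects, x$config$n_positive, x$config$n_reference,
    x$config$n_clinical))
  cat(sprintf("  grid %s, %d regions, %d timepoints\n",
              paste(x$config$grid_shape, collapse = "x"),
              x$config$n_regions, x$config$n_timepoints))
  invisible(x)
}

#' @export
`[.clinical_table` <- function(x, i, j, drop = FALSE) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    mask <- attr(x, "missing_mask")
    if (!is.null(mask)) {
      if (!missing(i)) mask <- mask[i, , drop = FALSE]
      if (!missing(j)) mask <- mask[, j, drop = FALSE]
      attr(out, "missing_mask") <- mask
    }
    kinds <- attr(x, "kinds")
    if (!is.null(kinds) && !missing(j)) attr(out, "kinds") <- kinds[j]
    class(out) <- c("clinical_table", "data.frame")
  }
  out
}
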