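# desk-sized cohort configurations used across the suite

tiny_config <- function(seed = 1, ...) {
  args <- list(n_subjects = 12, n_positive = 5, n_reference = 4,
               n_clinical = 8, grid_shape = c(4, 4, 4), n_regions = 4,
               n_timepoints = 24, n_missing_vars = 3, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(cohort_config, args)
}

tiny_null_config <- function(seed = 1, ...) {
  cfg <- tiny_config(seed = seed, ...)
  cfg$clinical_effect_sizes <- numeric(cfg$n_clinical)
  cfg$isc_attenuation <- rep(1, cfg$n_regions)
  cfg$vbm_effects <- numeric(cfg$n_regions)
  cfg
}

# linearly separable two-feature toy problem
separable_toy <- function(n_per_class = 6, seed = 42) {
  withr::with_seed(seed, {
    x <- cbind(f1 = c(rnorm(n_per_class, -1, 0.2), rnorm(n_per_class, 1, 0.2)),
               f2 = c(rnorm(n_per_class, 1, 0.2), rnorm(n_per_class, -1, 0.2)))
    list(x = x, y = rep(c(0L, 1L), each = n_per_class))
  })
}

# independent per-voxel, per-reference ISC oracle using stats::cor
isc_oracle <- function(subject_ts, reference_ts, eps = 1e-7) {
  v <- ncol(subject_ts)
  zbar <- numeric(v)
  for (vox in seq_len(v)) {
    zs <- numeric(length(reference_ts))
    for (j in seq_along(reference_ts)) {
      s <- subject_ts[, vox]
      r <- reference_ts[[j]][, vox]
      rho <- if (stats::sd(s) == 0 || stats::sd(r) == 0) 0
             else stats::cor(s, r)
      rho <- min(1 - eps, max(-(1 - eps), rho))
      zs[j] <- atanh(rho)
    }
    zbar[vox] <- mean(zs)
  }
  zbar
}

# independent per-region pooling oracle
pool_oracle <- function(map, atlas) {
  labs <- sort(unique(as.vector(atlas)))
  labs <- labs[labs >= 1]
  t(vapply(labs, function(r) {
    vals <- as.vector(map)[as.vector(atlas) == r]
    c(min = min(vals), max = max(vals), mean = mean(vals),
      sd = if (length(vals) > 1) stats::sd(vals) else 0)
  }, numeric(4)))
}

# tiny clinical table built by hand, for preprocessor tests
handmade_clinical <- function() {
  tab <- data.frame(
    smoker = c(1L, 0L, 1L, 0L, NA, 1L),
    nicotine_dep = c(6L, NA, 2L, NA, NA, NA),
    score = c(2, 4, NA, 6, 8, 10),
    stage = factor(c("a", "b", "a", NA, "c", "a"),
                   levels = c("a", "b", "c")),
    flag = c(1L, 1L, 0L, NA, 1L, 0L),
    row.names = sprintf("sub%03d", 1:6)
  )
  structure(tab,
            kinds = c(smoker = "binary", nicotine_dep = "scalar",
                      score = "scalar", stage = "categorical",
                      flag = "binary"),
            missing_mask = is.na(as.matrix(tab)),
            smoker_col = "smoker", nicotine_col = "nicotine_dep",
            class = c("clinical_table", "data.frame"))
}
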