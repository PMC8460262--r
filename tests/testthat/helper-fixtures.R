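# Shared desk-scale fixtures, built once per test run. Sizes are deliberately
# small; acceptance-scale cohorts are built inside test-acceptance.R.

fix_env <- new.env()

small_geometry <- function() {
  if (is.null(fix_env$geom)) {
    fix_env$geom <- generate_geometry(c(12, 12, 6), "ellipsoid")
  }
  fix_env$geom
}

small_atlas <- function() {
  if (is.null(fix_env$atlas)) {
    fix_env$atlas <- generate_component_maps(small_geometry(), K = 6,
                                             smoothness_fwhm = 2, seed = 11)
  }
  fix_env$atlas
}

# 4 planted states x 4 trials, short trials, default SNR.
small_cohort <- function() {
  if (is.null(fix_env$cohort)) {
    fix_env$cohort <- generate_cohort(
      small_geometry(), small_atlas(), default_state_profiles(),
      n_trials_per_state = c(4, 4, 4, 4), T_frames = 300, seed = 21)
  }
  fix_env$cohort
}

small_maps <- function() {
  if (is.null(fix_env$maps)) {
    fix_env$maps <- lapply(small_cohort()$trials, voxelwise_correlation)
  }
  fix_env$maps
}

# Noise-free single-component cohort for exact recovery checks.
noisefree_cohort <- function() {
  if (is.null(fix_env$nf)) {
    g <- small_geometry()
    atlas1 <- generate_component_maps(g, K = 1, smoothness_fwhm = 2, seed = 7)
    prof <- list(state_profile(1L, 1, 0.018))
    fix_env$nf <- generate_cohort(g, atlas1, prof, 4, T_frames = 300,
                                  noise_sd_fmri = 0, noise_sd_pupil = 0,
                                  seed = 31)
  }
  fix_env$nf
}

# Hand-written Pearson correlation, kept deliberately naive as an oracle.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
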