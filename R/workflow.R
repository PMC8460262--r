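# Configuration, I/O glue, and the end-to-end pipeline chaining synthetic
# generation, preprocessing, correlation maps, clustering, decoding, and
# significance mapping into a single report.

#' Zero-phase band-pass filter of a trial's fMRI
#'
#' Per voxel, an FFT-domain filter with the squared magnitude response of a
#' 4th-order Butterworth band-pass (default edges 0.002 and 0.15 Hz) is
#' applied with zero phase. FFT application avoids time-domain instability at
#' very low cutoffs and is exactly zero-phase by construction.
#'
#' @param trial a `Trial`.
#' @param low,high band edges in Hz; must satisfy `0 < low < high < Nyquist`.
#' @param order Butterworth order (default 4).
#' @return a filtered `Trial` (pupil trace untouched: only the fMRI carries
#'   the acquisition filter).
#' @export
bandpass_fmri <- function(trial, low = 0.002, high = 0.15, order = 4) {
  stopifnot(inherits(trial, "Trial"))
  nyq <- 1 / (2 * trial$tr)
  if (!(low > 0 && low < high && high < nyq)) {
    stop("invalid band: need 0 < low < high < Nyquist (", nyq, " Hz)")
  }
  T_ <- ncol(trial$fmri)
  f <- seq(0, T_ - 1) / (T_ * trial$tr)
  f <- pmin(f, 1 / trial$tr - f)
  H <- butterworth_magnitude(f, low, high, order)
  sp <- stats::mvfft(t(trial$fmri))
  filt <- Re(stats::mvfft(sp * H, inverse = TRUE)) / T_
  new_trial(trial$subject_id, t(filt), trial$pupil, trial$tr, trial$geometry)
}

#' @keywords internal
#' @noRd
butterworth_magnitude <- function(f, low, high, order) {
  hp <- ifelse(f == 0, 0, 1 / sqrt(1 + (low / pmax(f, 1e-12))^(2 * order)))
  lp <- 1 / sqrt(1 + (f / high)^(2 * order))
  hp * lp
}

#' Default pipeline configuration
#'
#' All generator, preprocessing, clustering, decoding, and significance
#' parameters with their desk-scale defaults, plus explicit seeds. Pass
#' overrides as named arguments.
#'
#' @param ... named overrides of any default.
#' @return object of class `PipelineConfig` (a named list).
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    shape = c(24L, 24L, 12L), mask_rule = "ellipsoid",
    K = 6L, smoothness_fwhm = 2,
    n_trials_per_state = c(8L, 30L, 24L, 12L),
    T_frames = 925L, tr = 1,
    noise_sd_fmri = 1.0, noise_sd_pupil = 0.3, osc_amplitude = 1.0,
    pupil_lag_frames = 0L,
    bandpass = c(0.002, 0.15),
    n_test_trials = 10L,
    k_range = 3:7, cluster_repeats = 100L, embed_method = "umap",
    n_components = 300L, ridge_alpha = 19861, n_folds = 4L,
    methods = c("template", "ridge"),
    gru = NULL,
    n_perm = 1000L, sig_alpha = 0.01,
    run_half_split = FALSE, half_split_repeats = 100L,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  nyq <- 1 / (2 * cfg$tr)
  if (!(cfg$bandpass[1] > 0 && cfg$bandpass[1] < cfg$bandpass[2] &&
        cfg$bandpass[2] < nyq)) {
    stop("bandpass edges must satisfy 0 < low < high < Nyquist")
  }
  structure(cfg, class = c("PipelineConfig", "list"))
}

#' Run the full synthetic pipeline
#'
#' Generate a cohort, band-pass the fMRI, build per-trial correlation maps,
#' cluster them into brain states (silhouette sweep + consensus), decode pupil
#' traces (cross-validated template / ridge / optional GRU on a held-out test
#' split), back-project the decoder into a prediction map with randomization
#' significance, and refit per-cluster maps. Returns a report list with every
#' score, label, and ground-truth recovery metric; all stages are seeded from
#' `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @param verbose print stage progress.
#' @return object of class `PipelineReport` (a nested list; see the vignette).
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  seed <- config$seed
  say("stage simulate")
  sim <- stage("simulate", {
    geom <- generate_geometry(config$shape, config$mask_rule)
    atlas <- generate_component_maps(geom, config$K, config$smoothness_fwhm,
                                     seed = substream_seed(seed, 1L))
    profiles <- default_state_profiles(config$K)[seq_along(config$n_trials_per_state)]
    generate_cohort(geom, atlas, profiles, config$n_trials_per_state,
                    T_frames = config$T_frames, tr = config$tr,
                    noise_sd_fmri = config$noise_sd_fmri,
                    noise_sd_pupil = config$noise_sd_pupil,
                    osc_amplitude = config$osc_amplitude,
                    pupil_lag_frames = config$pupil_lag_frames,
                    seed = substream_seed(seed, 2L))
  })
  trials <- sim$trials
  gt <- sim$ground_truth
  say("stage preprocess (%d trials)", length(trials))
  trials <- stage("preprocess", lapply(trials, bandpass_fmri,
                                       low = config$bandpass[1],
                                       high = config$bandpass[2]))
  say("stage corrmap")
  maps <- stage("corrmap", lapply(trials, voxelwise_correlation))
  all_map <- stage("corrmap", concatenated_map(trials))
  map_sims <- vapply(maps, spatial_similarity, numeric(1), b = all_map)
  n_states <- length(unique(gt$state_labels))
  clustering <- NULL
  if (n_states < 2) {
    say("stage cluster skipped: single planted state")
    clustering <- list(degenerate = TRUE,
                       note = "single planted state; clustering battery skipped")
  } else {
    say("stage cluster")
    clustering <- stage("cluster", {
      sweep <- silhouette_sweep(maps, k_range = config$k_range,
                                n_repeats = config$cluster_repeats,
                                seed = substream_seed(seed, 3L),
                                method = config$embed_method)
      cons <- consensus_labels(sweep$runs[[as.character(sweep$k_star)]])
      res <- list(degenerate = FALSE, k_star = sweep$k_star,
                  silhouette_table = sweep$table,
                  labels = cons$final_labels, stability = cons$stability,
                  ari_vs_truth = adjusted_rand_index(cons$final_labels,
                                                     gt$state_labels))
      if (config$run_half_split) {
        hs <- half_split_reproducibility(
          maps, cons$final_labels, k = sweep$k_star,
          n_repeats = config$half_split_repeats,
          seed = substream_seed(seed, 4L), method = config$embed_method)
        res$half_split_median_match <- stats::median(hs$match_ratios)
      }
      res
    })
  }
  say("stage decode")
  n_test <- min(config$n_test_trials, length(trials) - 4L)
  split_idx <- with_seed(substream_seed(seed, 5L),
                         sort(sample.int(length(trials), n_test)))
  test_trials <- trials[split_idx]
  train_trials <- trials[-split_idx]
  model_spec <- list(methods = config$methods,
                     n_components = config$n_components,
                     alpha = config$ridge_alpha, gru = config$gru)
  scores <- stage("decode", crossval(train_trials, model_spec,
                                     n_folds = config$n_folds,
                                     test_trials = test_trials,
                                     seed = substream_seed(seed, 6L)))
  say("stage maps")
  map_stage <- stage("maps", {
    models <- fit_decoders(train_trials, model_spec,
                           seed = substream_seed(seed, 6L))
    series <- lapply(train_trials, project, basis = models$basis)
    pupil <- lapply(train_trials, function(tr) normalize_variance(tr$pupil))
    sig <- randomization_significance(
      series, pupil, models$basis, alpha = config$sig_alpha,
      n_perm = config$n_perm, seed = substream_seed(seed, 7L),
      fit_fun = function(X, y) fit_linear(X, y, "ridge",
                                          alpha = config$ridge_alpha))
    train_labels <- if (!is.null(clustering$labels)) {
      clustering$labels[-split_idx]
    } else {
      gt$state_labels[-split_idx]
    }
    cl_maps <- suppressWarnings(
      per_cluster_maps(train_trials, train_labels, models$basis,
                       alpha = config$ridge_alpha))
    list(basis_evr = models$basis$explained_variance_ratio,
         observed = sig$observed$values,
         p_values = sig$p_map$values,
         n_significant_fdr = sum(sig$mask_fdr),
         cluster_maps = lapply(cl_maps, function(e) {
           list(n_trials = e$n_trials, map = e$map$values)
         }))
  })
  report <- list(
    config = unclass(config),
    n_trials = length(sim$trials),
    state_labels = gt$state_labels,
    map_similarity_to_all_trial = map_sims,
    clustering = clustering,
    decoding = list(
      scores = scores,
      mean_cv = stats::aggregate(r ~ method, scores[scores$split == "cv", ],
                                 mean),
      mean_test = if (any(scores$split == "test")) {
        stats::aggregate(r ~ method, scores[scores$split == "test", ], mean)
      } else {
        NULL
      }
    ),
    maps = map_stage
  )
  class(report) <- c("PipelineReport", "list")
  report
}

#' Validate the minimal schema of a pipeline report
#' @param report a [run_pipeline()] result.
#' @export
validate_report <- function(report) {
  need <- c("config", "n_trials", "state_labels", "clustering", "decoding",
            "maps")
  missing <- setdiff(need, names(report))
  if (length(missing) > 0) {
    stop("report is missing fields: ", paste(missing, collapse = ", "))
  }
  stopifnot(is.numeric(report$n_trials),
            length(report$state_labels) == report$n_trials,
            is.data.frame(report$decoding$scores))
  invisible(TRUE)
}
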