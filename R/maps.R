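# Back-projection of decoders into voxel-wise pupil-information maps,
# randomization-test significance with FDR control, per-component variance
# attribution, and per-cluster map refitting.

#' Integrate linear decoder weights into a voxel map
#'
#' `m(v) = (1/K) sum_k w_k C_k(v)`: PCA component maps weighted by their
#' decoder weights, summed, and scaled by 1/K. The global scale is a
#' convention; the spatial pattern is the contract.
#'
#' @param basis a [fit_pca()] `PCABasis`.
#' @param decoder a [fit_linear()] `LinearDecoder` (component counts must
#'   match).
#' @return a `SpatialMap` of kind `"prediction"` with attribute `source`.
#' @export
integrate_linear_map <- function(basis, decoder) {
  stopifnot(inherits(basis, "PCABasis"), inherits(decoder, "LinearDecoder"))
  if (length(decoder$weights) != basis$n_components) {
    stop("component count mismatch: basis has ", basis$n_components,
         ", decoder has ", length(decoder$weights))
  }
  v <- integrate_weights(basis, decoder$weights)
  m <- new_spatial_map(v, basis$geometry, "prediction")
  attr(m, "source") <- "linear_weights"
  m
}

#' @keywords internal
#' @noRd
integrate_weights <- function(basis, w) {
  as.numeric(crossprod(basis$spatial_components, w)) / basis$n_components
}

#' Integrate GRU input sensitivities into a voxel map
#'
#' Mean gradients of the predictions with respect to each input component
#' ([gru_input_sensitivities()]) replace the linear weights in
#' [integrate_linear_map()].
#'
#' @param basis a `PCABasis`.
#' @param decoder a `GRUDecoder` trained on this basis.
#' @param series list of `ComponentSeries` over which sensitivities are
#'   averaged (typically the training trials).
#' @export
integrate_gru_map <- function(basis, decoder, series) {
  stopifnot(inherits(basis, "PCABasis"), inherits(decoder, "GRUDecoder"))
  if (decoder$n_input != basis$n_components) {
    stop("component count mismatch: basis has ", basis$n_components,
         ", decoder has ", decoder$n_input)
  }
  sens <- gru_input_sensitivities(decoder, series)
  v <- integrate_weights(basis, sens)
  m <- new_spatial_map(v, basis$geometry, "prediction")
  attr(m, "source") <- "gru_gradients"
  m
}

#' Benjamini-Hochberg false discovery rate mask
#'
#' Step-up procedure at level `q`: sort the p values, find the largest i with
#' `p_(i) <= i q / m`, and select everything at or below that rank.
#'
#' @param p_values numeric in \[0, 1\].
#' @param q FDR level (default 0.01).
#' @return logical mask, TRUE where the adjusted p value is <= `q`.
#' @export
fdr_correct <- function(p_values, q = 0.01) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  m <- length(p_values)
  ord <- order(p_values)
  thresh <- q * seq_len(m) / m
  below <- p_values[ord] <= thresh
  mask <- logical(m)
  if (any(below)) {
    cutoff <- max(which(below))
    mask[ord[seq_len(cutoff)]] <- TRUE
  }
  mask
}

#' Randomization-test significance for a prediction map
#'
#' Null maps are built by refitting the decoder after randomly reassigning
#' whole pupil traces across trials (`n_perm` times); a voxel's two-sided
#' empirical p value uses the +1-corrected counting estimator
#' `p = 2 min(#(null >= obs) + 1, #(null <= obs) + 1) / (n_perm + 1)` (capped
#' at 1). A voxel is flagged significant when its observed value is at or
#' beyond the null's `alpha/2` or `1 - alpha/2` quantile, and the p values are
#' additionally FDR-masked at `q = alpha`.
#'
#' @param series list of `ComponentSeries` (training trials projected on a
#'   fixed basis).
#' @param pupil list of variance-normalized pupil traces, parallel to
#'   `series`.
#' @param basis the `PCABasis` used for back-projection.
#' @param alpha two-sided significance level / FDR level (default 0.01).
#' @param n_perm number of permutations (>= 100; desk default 1000; 10000 for
#'   full-scale runs).
#' @param seed integer seed.
#' @param fit_fun decoder fitter mapping `(X, y)` to a `LinearDecoder`
#'   (default ridge, alpha = 19861).
#' @return list: `observed` (`SpatialMap`), `p_map` (`SpatialMap`, kind
#'   `"pvalue"`), `mask_quantile`, `mask_fdr` (logical per voxel), `n_perm`.
#' @export
randomization_significance <- function(series, pupil, basis, alpha = 0.01,
                                       n_perm = 1000, seed = 1,
                                       fit_fun = NULL) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  stopifnot(length(series) == length(pupil), length(series) >= 2)
  if (is.null(fit_fun)) {
    fit_fun <- function(X, y) fit_linear(X, y, variant = "ridge", alpha = 19861)
  }
  mats <- lapply(series, function(s) if (inherits(s, "ComponentSeries")) s$scores else as.matrix(s))
  Xcat <- do.call(cbind, mats)
  build_map <- function(pupil_list) {
    y <- unlist(pupil_list)
    integrate_weights(basis, fit_fun(Xcat, y)$weights)
  }
  obs <- build_map(pupil)
  nv <- length(obs)
  ge <- integer(nv) # count of null >= observed
  le <- integer(nv)
  n_tr <- length(pupil)
  for (b in seq_len(n_perm)) {
    perm <- with_seed(substream_seed(seed, b), sample.int(n_tr))
    nm <- build_map(pupil[perm])
    ge <- ge + (nm >= obs)
    le <- le + (nm <= obs)
  }
  p <- pmin(1, 2 * pmin(ge + 1, le + 1) / (n_perm + 1))
  # "at or beyond the alpha/2 tail of the null" by exact counting: level is
  # <= alpha under exchangeability (quantile interpolation would inflate it)
  mask_q <- p <= alpha
  mask_fdr <- fdr_correct(p, q = alpha)
  list(observed = new_spatial_map(obs, basis$geometry, "prediction"),
       p_map = new_spatial_map(p, basis$geometry, "pvalue"),
       mask_quantile = mask_q, mask_fdr = mask_fdr, n_perm = n_perm)
}

#' Pupil variance explained by each PCA component
#'
#' Following the shuffle-attribution scheme: for component k, the time points
#' of all *other* component rows are randomly shuffled (destroying their
#' information while preserving their marginal distributions), a ridge decoder
#' (`alpha` as published) is fitted on the shuffled design under
#' cross-validation, and the out-of-fold explained variance of the pupil trace
#' is recorded. Shuffles are redrawn per fold. The fMRI-side variance ratios
#' are read off the PCA basis.
#'
#' @param X `n_components x T` component series (variance-normalized rows).
#' @param y length-`T` pupil trace.
#' @param alpha ridge penalty (default 19861).
#' @param n_folds cross-validation folds (default 4).
#' @param seed integer seed (fold split and shuffles).
#' @param basis optional `PCABasis` supplying `explained_variance_ratio`.
#' @return object of class `ExplainedVariance`: data.frame with `component`,
#'   `pupil_ev` (may be <= 0 for uninformative components), `fmri_evr` (NA
#'   without a basis).
#' @export
explained_variance_by_component <- function(X, y, alpha = 19861, n_folds = 4,
                                            seed = 1, basis = NULL) {
  X <- as.matrix(X)
  K <- nrow(X)
  T_ <- ncol(X)
  stopifnot(K >= 2, length(y) == T_)
  folds <- split(seq_len(T_), rep(seq_len(n_folds), length.out = T_))
  ev <- numeric(K)
  for (k in seq_len(K)) {
    ss_res <- 0; ss_tot <- 0
    for (f in seq_along(folds)) {
      test <- folds[[f]]
      Xs <- X
      others <- setdiff(seq_len(K), k)
      Xs[others, ] <- with_seed(substream_seed(seed, k * 100L + f), {
        t(apply(X[others, , drop = FALSE], 1, function(row) row[sample.int(T_)]))
      })
      dec <- fit_linear(Xs[, -test, drop = FALSE], y[-test],
                        variant = "ridge", alpha = alpha)
      pred <- predict(dec, Xs[, test, drop = FALSE])
      ss_res <- ss_res + sum((y[test] - pred)^2)
      ss_tot <- ss_tot + sum((y[test] - mean(y[-test]))^2)
    }
    ev[k] <- 1 - ss_res / ss_tot
  }
  fmri_evr <- if (!is.null(basis)) {
    basis$explained_variance_ratio[seq_len(K)]
  } else {
    rep(NA_real_, K)
  }
  structure(data.frame(component = seq_len(K), pupil_ev = ev,
                       fmri_evr = fmri_evr),
            class = c("ExplainedVariance", "data.frame"))
}

#' Per-cluster prediction maps
#'
#' For each cluster with at least `min_trials` members, the linear decoder is
#' refitted on that cluster's trials only (on the shared PCA basis fitted to
#' all training trials), back-projected into a map, and optionally assessed
#' with the randomization test within the cluster. Undersized clusters are
#' skipped with a warning.
#'
#' @param trials list of `Trial` objects.
#' @param cluster_labels integer labels parallel to `trials`.
#' @param basis shared `PCABasis` (fitted on all training trials).
#' @param alpha ridge penalty (default 19861).
#' @param min_trials minimum cluster size (default 3).
#' @param significance logical: run [randomization_significance()] per cluster.
#' @param n_perm,sig_alpha,seed forwarded to the significance test.
#' @return named list (one entry per retained cluster): `map`, `n_trials`,
#'   `decoder`, and (if requested) `significance`.
#' @export
per_cluster_maps <- function(trials, cluster_labels, basis, alpha = 19861,
                             min_trials = 3, significance = FALSE,
                             n_perm = 1000, sig_alpha = 0.01, seed = 1) {
  stopifnot(length(trials) == length(cluster_labels))
  out <- list()
  for (cl in sort(unique(cluster_labels))) {
    idx <- which(cluster_labels == cl)
    if (length(idx) < min_trials) {
      warning("cluster ", cl, " has only ", length(idx),
              " trials (< ", min_trials, "); skipped")
      next
    }
    series <- lapply(trials[idx], project, basis = basis)
    pupil <- lapply(trials[idx], function(tr) normalize_variance(tr$pupil))
    Xcat <- do.call(cbind, lapply(series, function(s) s$scores))
    ycat <- unlist(pupil)
    dec <- fit_linear(Xcat, ycat, variant = "ridge", alpha = alpha)
    entry <- list(map = integrate_linear_map(basis, dec),
                  n_trials = length(idx), decoder = dec)
    if (significance) {
      entry$significance <- randomization_significance(
        series, pupil, basis, alpha = sig_alpha, n_perm = n_perm,
        seed = substream_seed(seed, cl),
        fit_fun = function(X, y) fit_linear(X, y, variant = "ridge",
                                            alpha = alpha))
    }
    out[[as.character(cl)]] <- entry
  }
  out
}
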