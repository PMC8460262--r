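# Decoding pupil traces from fMRI: PCA feature extraction, correlation
# template baseline, linear-regression variants, cross-validation, shift and
# component-count sweeps, paired method comparison.

#' Fit a PCA basis on training trials
#'
#' Principal components of the time-concatenated training voxel matrix
#' (voxels are the variables). Deterministic up to component sign; signs are
#' fixed so each component's maximum-|loading| voxel is positive.
#'
#' @param training_trials list of `Trial` objects sharing one geometry.
#' @param n_components number of components to keep (default 300, capped at
#'   the data rank).
#' @return object of class `PCABasis`: `spatial_components`
#'   (`n_components x n_voxels`), `mean_map`, `explained_variance_ratio`,
#'   `n_components`, `geometry`.
#' @export
fit_pca <- function(training_trials, n_components = 300) {
  stopifnot(length(training_trials) >= 1)
  geom <- training_trials[[1]]$geometry
  X <- t(do.call(cbind, lapply(training_trials, function(tr) tr$fmri)))
  # X: total_frames x n_voxels
  if (nrow(X) < n_components) {
    stop("n_components = ", n_components, " exceeds total training frames (",
         nrow(X), ")")
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  max_rank <- min(dim(Xc)) - 1L
  if (n_components > max_rank) {
    stop("n_components = ", n_components, " exceeds the data rank bound (",
         max_rank, ")")
  }
  if (ncol(Xc) <= nrow(Xc)) {
    ev <- eigen(crossprod(Xc), symmetric = TRUE)
    vals <- pmax(ev$values, 0)
    comps <- t(ev$vectors[, seq_len(n_components), drop = FALSE])
  } else {
    ev <- eigen(tcrossprod(Xc), symmetric = TRUE)
    vals <- pmax(ev$values, 0)
    u <- ev$vectors[, seq_len(n_components), drop = FALSE]
    comps <- t(crossprod(Xc, u) %*% diag(1 / sqrt(vals[seq_len(n_components)]),
                                         n_components, n_components))
  }
  # sign convention: max-|loading| voxel positive
  for (j in seq_len(n_components)) {
    v <- comps[j, ]
    if (v[which.max(abs(v))] < 0) comps[j, ] <- -v
  }
  evr <- vals / sum(vals)
  structure(list(spatial_components = comps, mean_map = mu,
                 explained_variance_ratio = evr[seq_len(n_components)],
                 n_components = as.integer(n_components), geometry = geom),
            class = "PCABasis")
}

#' Project a trial onto a PCA basis
#'
#' `scores = components %*% (voxels - mean_map)`, then per-component variance
#' normalization (constant rows are flagged and set to zero).
#'
#' @param trial a `Trial` (geometry must match the basis).
#' @param basis a [fit_pca()] object.
#' @return object of class `ComponentSeries`: `scores`
#'   (`n_components x T`, each non-constant row mean 0 / variance 1),
#'   `constant_rows` (logical).
#' @export
project <- function(trial, basis) {
  stopifnot(inherits(trial, "Trial"), inherits(basis, "PCABasis"))
  if (nrow(trial$fmri) != length(basis$mean_map)) {
    stop("trial geometry does not match the PCA basis")
  }
  sc <- basis$spatial_components %*% (trial$fmri - basis$mean_map)
  sds <- apply(sc, 1, stats::sd)
  # relative threshold: rows that only carry numerical residue are "constant"
  const <- !is.finite(sds) | sds <= max(1e-12, max(sds, na.rm = TRUE) * 1e-8)
  sc <- (sc - rowMeans(sc)) / ifelse(const, 1, sds)
  sc[const, ] <- 0
  structure(list(scores = sc, constant_rows = const),
            class = "ComponentSeries")
}

#' Correlation-template pupil prediction
#'
#' Per time point, the Pearson correlation across voxels between a fixed
#' template map (built from training data only) and that time point's volume.
#' Predictions are bounded to \[-1, 1\]; constant volumes yield 0 and are
#' flagged.
#'
#' @param template a `SpatialMap`.
#' @param trial a `Trial` on the same geometry.
#' @export
template_predict <- function(template, trial) {
  stopifnot(inherits(template, "SpatialMap"), inherits(trial, "Trial"),
            nrow(trial$fmri) == length(template$values))
  r <- rowwise_pearson(t(trial$fmri), template$values)
  pmin(1, pmax(-1, as.numeric(r)))
}

#' Fit a linear pupil decoder on concatenated component series
#'
#' Rows of `X` are component time courses (already standardized per trial),
#' columns are concatenated frames; `y` is the concatenated pupil trace.
#' The default variant is ridge with the regularization weight
#' `alpha = 19861` — solved in closed form from the normal equations
#' `(X X^T + alpha I) w = X y` on centered data, with the intercept recovered
#' from the means. `ols` uses QR; `lasso`/`elastic-net` delegate to glmnet
#' with `lambda = alpha / n_samples`.
#'
#' @param X `n_components x total_frames` matrix.
#' @param y length-`total_frames` numeric.
#' @param variant one of `"ridge"`, `"ols"`, `"lasso"`, `"elastic-net"`.
#' @param alpha regularization weight (>= 0); ignored for `ols`.
#' @return object of class `LinearDecoder`: `variant`, `alpha`, `weights`,
#'   `intercept`.
#' @export
fit_linear <- function(X, y, variant = c("ridge", "ols", "lasso", "elastic-net"),
                       alpha = 19861) {
  variant <- match.arg(variant)
  stopifnot(ncol(X) == length(y), alpha >= 0)
  Xmean <- rowMeans(X)
  ymean <- mean(y)
  Xc <- X - Xmean
  yc <- y - ymean
  if (variant == "ridge") {
    A <- tcrossprod(Xc)
    diag(A) <- diag(A) + alpha
    w <- solve(A, Xc %*% yc)
  } else if (variant == "ols") {
    qrX <- qr(t(Xc))
    if (qrX$rank < nrow(X)) {
      stop("singular OLS system (rank ", qrX$rank, " < ", nrow(X),
           "); use ridge")
    }
    w <- qr.coef(qrX, yc)
  } else {
    mix <- if (variant == "lasso") 1 else 0.5
    fit <- glmnet::glmnet(t(Xc), yc, alpha = mix,
                          lambda = alpha / length(y), standardize = FALSE,
                          intercept = FALSE)
    w <- as.numeric(fit$beta)
  }
  w <- as.numeric(w)
  structure(list(variant = variant, alpha = alpha, weights = w,
                 intercept = ymean - sum(w * Xmean)),
            class = "LinearDecoder")
}

#' Predict a pupil trace with a fitted decoder
#' @param object a `LinearDecoder` or `GRUDecoder`.
#' @param X a `ComponentSeries` or `n_components x T` matrix.
#' @param ... unused.
#' @export
predict.LinearDecoder <- function(object, X, ...) {
  S <- if (inherits(X, "ComponentSeries")) X$scores else as.matrix(X)
  if (nrow(S) != length(object$weights)) {
    stop("component count mismatch: decoder has ", length(object$weights),
         ", input has ", nrow(S))
  }
  as.numeric(object$weights %*% S) + object$intercept
}

#' Paired t-test between two sets of per-trial prediction scores
#' @param scores_a,scores_b numeric vectors paired by trial (>= 3 pairs).
#' @return list with `t`, `p`, `df`, `mean_diff`, `degenerate` flag.
#' @export
compare_methods <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) == length(scores_b))
  n <- length(scores_a)
  if (n < 3) stop("paired comparison needs at least 3 pairs")
  d <- scores_a - scores_b
  if (stats::sd(d) <= 1e-12 * (abs(mean(d)) + 1)) {
    return(list(t = if (all(d == 0)) 0 else sign(mean(d)) * Inf,
                p = if (all(d == 0)) 1 else 0,
                df = n - 1, mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(scores_a, scores_b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       mean_diff = mean(d), degenerate = FALSE)
}

#' @keywords internal
#' @noRd
make_folds <- function(n, n_folds, seed) {
  idx <- with_seed(substream_seed(seed, 31L), sample.int(n))
  split(idx, rep(seq_len(n_folds), length.out = n))
}

# Fit decoders named in model_spec on a list of trials; returns fitted models
# plus the basis/template so callers can score held-out trials.
#' @keywords internal
#' @noRd
fit_decoders <- function(train_trials, model_spec, seed) {
  n_comp <- min(model_spec$n_components,
                sum(vapply(train_trials, function(tr) ncol(tr$fmri),
                           numeric(1))) - 1,
                nrow(train_trials[[1]]$fmri) - 1)
  basis <- fit_pca(train_trials, n_components = n_comp)
  series <- lapply(train_trials, project, basis = basis)
  Xcat <- do.call(cbind, lapply(series, function(s) s$scores))
  ycat <- unlist(lapply(train_trials, function(tr) normalize_variance(tr$pupil)))
  out <- list(basis = basis)
  if ("template" %in% model_spec$methods) {
    out$template <- concatenated_map(train_trials)
  }
  if ("ridge" %in% model_spec$methods) {
    out$ridge <- fit_linear(Xcat, ycat, variant = model_spec$variant %||% "ridge",
                            alpha = model_spec$alpha %||% 19861)
  }
  if ("gru" %in% model_spec$methods) {
    ys <- lapply(train_trials, function(tr) normalize_variance(tr$pupil))
    out$gru <- fit_gru(series, ys, config = model_spec$gru %||% gru_config(),
                       seed = substream_seed(seed, 77L))
  }
  out
}

#' @keywords internal
#' @noRd
score_trials <- function(models, trials, model_spec) {
  rows <- list()
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    y <- tr$pupil
    s <- project(tr, models$basis)
    if (!is.null(models$template)) {
      pred <- template_predict(models$template, tr)
      rows[[length(rows) + 1]] <- data.frame(
        trial = tr$subject_id, method = "template", r = pearson(pred, y))
    }
    if (!is.null(models$ridge)) {
      pred <- predict(models$ridge, s)
      rows[[length(rows) + 1]] <- data.frame(
        trial = tr$subject_id, method = "ridge", r = pearson(pred, y))
    }
    if (!is.null(models$gru)) {
      pred <- predict(models$gru, s)
      rows[[length(rows) + 1]] <- data.frame(
        trial = tr$subject_id, method = "gru", r = pearson(pred, y))
    }
  }
  do.call(rbind, rows)
}

#' Cross-validated decoding with a held-out test set
#'
#' Training trials are partitioned into `n_folds` folds; per fold, the PCA
#' basis, template map and decoders are fitted on the fold-training trials
#' only and scored on the fold-validation trials (no leakage: the basis and
#' template are rebuilt per fold). A final model fitted on all training trials
#' is scored on the disjoint test set.
#'
#' @param trials list of training `Trial` objects.
#' @param model_spec list: `methods` (subset of `"template"`, `"ridge"`,
#'   `"gru"`), `n_components`, `alpha`, optional `variant` and `gru` config.
#' @param n_folds number of folds (default 4).
#' @param test_trials optional list of held-out `Trial`s (must be disjoint
#'   from `trials` by `subject_id`).
#' @param seed integer seed (fold assignment, GRU init).
#' @return data.frame with columns `trial`, `method`, `split` (`"cv"` or
#'   `"test"`), `fold`, `r`.
#' @export
crossval <- function(trials, model_spec = list(methods = c("template", "ridge"),
                                               n_components = 300,
                                               alpha = 19861),
                     n_folds = 4, test_trials = NULL, seed = 1) {
  ids <- vapply(trials, function(tr) tr$subject_id, character(1))
  if (!is.null(test_trials)) {
    tids <- vapply(test_trials, function(tr) tr$subject_id, character(1))
    if (length(intersect(ids, tids)) > 0) {
      stop("trial leakage: ", paste(intersect(ids, tids), collapse = ", "),
           " appear in both training and test sets")
    }
  }
  folds <- make_folds(length(trials), n_folds, seed)
  out <- list()
  for (f in seq_along(folds)) {
    val_idx <- folds[[f]]
    models <- fit_decoders(trials[-val_idx], model_spec,
                           seed = substream_seed(seed, f))
    sc <- score_trials(models, trials[val_idx], model_spec)
    sc$split <- "cv"; sc$fold <- f
    out[[length(out) + 1]] <- sc
  }
  if (!is.null(test_trials)) {
    models <- fit_decoders(trials, model_spec, seed = substream_seed(seed, 0L))
    sc <- score_trials(models, test_trials, model_spec)
    sc$split <- "test"; sc$fold <- NA_integer_
    out[[length(out) + 1]] <- sc
  }
  do.call(rbind, out)
}

#' Sweep the temporal shift between fMRI and pupil
#'
#' For each shift `s` (frames), the pupil trace is advanced (`s > 0`: pupil
#' sample `t + s` is paired with fMRI frame `t`) with the overhang trimmed on
#' both series, and the full cross-validation is re-run. A cohort generated
#' with the pupil lagging the latents by `L` frames scores best at `s = L`.
#'
#' @param trials list of `Trial` objects.
#' @param shifts integer frame offsets (|shift| <= T/4).
#' @param model_spec,n_folds,seed as in [crossval()].
#' @return data.frame with `shift` and `mean_r` (mean cv score), plus the per
#'   trial scores as attribute `"scores"`.
#' @export
shift_sweep <- function(trials, shifts = -5:5,
                        model_spec = list(methods = "ridge",
                                          n_components = 50, alpha = 19861),
                        n_folds = 4, seed = 1) {
  T_ <- ncol(trials[[1]]$fmri)
  stopifnot(all(abs(shifts) <= T_ / 4))
  res <- list()
  for (s in shifts) {
    shifted <- lapply(trials, function(tr) {
      T_ <- ncol(tr$fmri)
      if (s >= 0) {
        fm <- tr$fmri[, seq_len(T_ - s), drop = FALSE]
        pu <- tr$pupil[(1 + s):T_]
      } else {
        fm <- tr$fmri[, (1 - s):T_, drop = FALSE]
        pu <- tr$pupil[seq_len(T_ + s)]
      }
      new_trial(tr$subject_id, fm, pu, tr$tr, tr$geometry)
    })
    sc <- crossval(shifted, model_spec, n_folds = n_folds, seed = seed)
    res[[length(res) + 1]] <- data.frame(shift = s, mean_r = mean(sc$r))
  }
  do.call(rbind, res)
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
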