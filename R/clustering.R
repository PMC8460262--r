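# Brain-state clustering of per-trial correlation maps: neighbor-graph
# embedding, Gaussian mixture modeling, silhouette model selection, consensus
# over repeated initializations, and reproducibility batteries.

#' Embed correlation maps in a low-dimensional space
#'
#' The default method is the stochastic neighbor-graph embedding (UMAP, via
#' uwot) with the settings used for map clustering: `n_neighbors = 7`,
#' `min_dist = 0`, and target dimension `D = min(72, n_trials - 2)` (the
#' method's upper bound given n input points). A deterministic PCA embedding
#' is selectable for fully reproducible tests.
#'
#' @param maps list of `SpatialMap` objects (or an `n_trials x n_features`
#'   matrix).
#' @param D target dimension; must satisfy `D <= n_trials - 2`.
#' @param n_neighbors neighbor count for the graph (default 7).
#' @param min_dist minimum embedded distance (default 0).
#' @param seed integer seed (drives the stochastic method).
#' @param method `"umap"` (stochastic) or `"pca"` (deterministic fallback).
#' @return object of class `Embedding`: list with `points`
#'   (`n_trials x D`), `D`, `method`, `method_params`.
#' @export
embed_maps <- function(maps, D = NULL, n_neighbors = 7, min_dist = 0,
                       seed = 1, method = c("umap", "pca")) {
  method <- match.arg(method)
  X <- maps_to_matrix(maps)
  n <- nrow(X)
  if (is.null(D)) D <- min(72L, n - 2L)
  if (D > n - 2) {
    stop("target dimension D = ", D, " exceeds the n_trials - 2 = ", n - 2,
         " bound")
  }
  stopifnot(n_neighbors < n, D >= 1)
  if (method == "pca") {
    Xc <- scale(X, center = TRUE, scale = FALSE)
    sv <- svd(Xc)
    r <- sum(sv$d > sv$d[1] * 1e-12)
    keep <- min(D, r)
    pts <- matrix(0, n, D) # dimensions beyond the data rank stay at zero
    pts[, seq_len(keep)] <- sv$u[, seq_len(keep), drop = FALSE] %*%
      diag(sv$d[seq_len(keep)], keep, keep)
  } else {
    init <- if (D <= n / 2) "spectral" else if (D <= ncol(X)) "pca" else "rand"
    pts <- with_seed(substream_seed(seed, 0L), {
      uwot::umap(X, n_components = D, n_neighbors = n_neighbors,
                 min_dist = min_dist, init = init,
                 n_threads = 1, n_sgd_threads = 1, batch = FALSE,
                 verbose = FALSE)
    })
  }
  if (any(!is.finite(pts))) stop("non-finite embedding coordinates")
  structure(list(points = unname(as.matrix(pts)), D = as.integer(D),
                 method = method,
                 method_params = list(n_neighbors = n_neighbors,
                                      min_dist = min_dist, seed = seed)),
            class = "Embedding")
}

#' @keywords internal
#' @noRd
maps_to_matrix <- function(maps) {
  if (is.matrix(maps)) return(maps)
  stopifnot(is.list(maps), length(maps) >= 1)
  do.call(rbind, lapply(maps, function(m) {
    if (inherits(m, "SpatialMap")) m$values else as.numeric(m)
  }))
}

#' Fit a Gaussian mixture model and score the clustering
#'
#' Full-covariance mixture fitted by expectation-maximization (k-means
#' initialization, covariance regularization 1e-6, tolerance 1e-3 on mean
#' log-likelihood, at most 100 iterations; one initialization per call —
#' run-to-run variability is what the consensus step aggregates). Hard labels
#' by maximum posterior; silhouettes on the embedding coordinates with
#' Euclidean distance.
#'
#' @param emb an [embed_maps()] `Embedding` (or bare coordinate matrix).
#' @param k number of mixture components (2 <= k <= n/2).
#' @param seed integer seed.
#' @return object of class `ClusterResult`: `labels` (1..k), `k`,
#'   `mean_silhouette`, `per_trial_silhouette`, `loglik`.
#' @export
fit_gmm <- function(emb, k, seed = 1) {
  X <- if (inherits(emb, "Embedding")) emb$points else as.matrix(emb)
  n <- nrow(X)
  stopifnot(k >= 2, k <= n / 2)
  res <- NULL
  for (attempt in 1:5) {
    res <- tryCatch(
      gmm_em(X, k, seed = substream_seed(seed, attempt)),
      error = function(e) NULL
    )
    if (!is.null(res) && length(unique(res$labels)) == k) break
    res <- NULL
  }
  if (is.null(res)) {
    stop("EM failed to produce k = ", k, " non-empty clusters after retries")
  }
  sil <- silhouette_scores(X, res$labels)
  structure(list(labels = res$labels, k = as.integer(k),
                 mean_silhouette = mean(sil), per_trial_silhouette = sil,
                 loglik = res$loglik),
            class = "ClusterResult")
}

#' @keywords internal
#' @noRd
gmm_em <- function(X, k, seed, reg_covar = 1e-6, tol = 1e-3, max_iter = 100) {
  n <- nrow(X); d <- ncol(X)
  km <- with_seed(seed, stats::kmeans(X, centers = k, nstart = 5,
                                      iter.max = 50))
  resp <- matrix(1e-10, n, k)
  resp[cbind(seq_len(n), km$cluster)] <- 1
  resp <- resp / rowSums(resp)
  log_gauss <- function(mu, sigma) {
    ch <- tryCatch(chol(sigma), error = function(e) NULL)
    if (is.null(ch)) stop("degenerate covariance")
    logdet <- 2 * sum(log(diag(ch)))
    Xc <- sweep(X, 2, mu)
    z <- backsolve(ch, t(Xc), transpose = TRUE)
    -0.5 * (d * log(2 * pi) + logdet + colSums(z^2))
  }
  prev_ll <- -Inf
  for (iter in seq_len(max_iter)) {
    # M-step
    nk <- colSums(resp)
    w <- nk / n
    logp <- matrix(0, n, k)
    for (j in seq_len(k)) {
      mu <- colSums(resp[, j] * X) / nk[j]
      Xc <- sweep(X, 2, mu)
      sigma <- crossprod(Xc * resp[, j], Xc) / nk[j] + diag(reg_covar, d)
      logp[, j] <- log(w[j]) + log_gauss(mu, sigma)
    }
    # E-step with log-sum-exp
    mx <- apply(logp, 1, max)
    lse <- mx + log(rowSums(exp(logp - mx)))
    resp <- exp(logp - lse)
    ll <- mean(lse)
    if (is.finite(prev_ll) && abs(ll - prev_ll) < tol) break
    prev_ll <- ll
  }
  list(labels = max.col(resp), loglik = ll)
}

#' Per-point silhouette scores
#'
#' `s_i = (b_i - a_i) / max(a_i, b_i)` with `a_i` the mean distance to the
#' point's own cluster and `b_i` the smallest mean distance to another
#' cluster; singletons score 0.
#' @param X coordinate matrix.
#' @param labels integer cluster labels.
#' @export
silhouette_scores <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(labels) == n)
  d <- as.matrix(stats::dist(X))
  ul <- sort(unique(labels))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    n_own <- sum(own) - 1
    if (n_own == 0) { s[i] <- 0; next }
    a <- sum(d[i, own]) / n_own
    b <- Inf
    for (l in ul) {
      if (l == labels[i]) next
      b <- min(b, mean(d[i, labels == l]))
    }
    s[i] <- (b - a) / max(a, b)
  }
  s
}

#' Silhouette sweep over cluster counts
#'
#' For each k in `k_range`, `n_repeats` independent embed+cluster runs
#' (re-seeded embedding and EM per repeat); the selected `k_star` maximizes
#' the mean silhouette.
#'
#' @param maps list of `SpatialMap`s or a matrix (rows = trials).
#' @param k_range candidate cluster counts (default 3:7).
#' @param n_repeats runs per k (default 100).
#' @param seed integer seed.
#' @param method,D,n_neighbors,min_dist forwarded to [embed_maps()].
#' @return list with `k_star`, `table` (k, mean, sd of mean silhouette),
#'   `runs` (per k, an `n_repeats x n_trials` label matrix, reusable by
#'   [consensus_labels()]).
#' @export
silhouette_sweep <- function(maps, k_range = 3:7, n_repeats = 100, seed = 1,
                             method = "umap", D = NULL, n_neighbors = 7,
                             min_dist = 0) {
  X <- maps_to_matrix(maps)
  n <- nrow(X)
  runs <- list()
  means <- sds <- numeric(length(k_range))
  sil_mat <- matrix(NA_real_, n_repeats, length(k_range))
  labels_arr <- lapply(k_range, function(k) matrix(NA_integer_, n_repeats, n))
  names(labels_arr) <- as.character(k_range)
  for (r in seq_len(n_repeats)) {
    emb <- embed_maps(X, D = D, n_neighbors = n_neighbors,
                      min_dist = min_dist,
                      seed = substream_seed(seed, r), method = method)
    for (ki in seq_along(k_range)) {
      cr <- fit_gmm(emb, k_range[ki], seed = substream_seed(seed, r * 1000L + ki))
      sil_mat[r, ki] <- cr$mean_silhouette
      labels_arr[[ki]][r, ] <- cr$labels
    }
  }
  means <- colMeans(sil_mat)
  sds <- apply(sil_mat, 2, stats::sd)
  if (n_repeats == 1) sds[] <- NA_real_
  tab <- data.frame(k = k_range, mean_silhouette = means, sd_silhouette = sds)
  list(k_star = k_range[which.max(means)], table = tab, runs = labels_arr,
       silhouettes = sil_mat)
}

#' Optimal alignment of one labeling onto another
#'
#' Relabels `b` by the permutation of its labels that maximizes agreement with
#' `a` (exhaustive search on the contingency table; cluster counts here are
#' small).
#' @param a,b integer labelings of the same trials with labels in 1..k.
#' @return `b` relabeled.
#' @export
align_labels <- function(a, b) {
  stopifnot(length(a) == length(b))
  k <- max(a, b)
  if (k > 8) stop("exhaustive alignment supports k <= 8")
  tab <- matrix(0L, k, k)
  for (i in seq_along(a)) tab[a[i], b[i]] <- tab[a[i], b[i]] + 1L
  perms <- permutations(k)
  best <- 1L; best_score <- -1L
  for (p in seq_len(nrow(perms))) {
    sc <- sum(tab[cbind(perms[p, ], seq_len(k))])
    if (sc > best_score) { best_score <- sc; best <- p }
  }
  perms[best, ][b]
}

#' Fraction of trials with matching labels after optimal alignment
#' @param a,b labelings of the same trials.
#' @export
label_match_ratio <- function(a, b) {
  mean(align_labels(a, b) == a)
}

#' Adjusted Rand index between two partitions
#' @param a,b labelings of the same points.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  mx <- (si + sj) / 2
  if (mx == expected) return(1)
  (sij - expected) / (mx - expected)
}

#' Consensus labels across repeated clustering runs
#'
#' Runs are aligned to the first run by optimal label matching, then each
#' trial receives its majority label (ties broken toward the lowest aligned
#' label index). Per-trial stability is the fraction of aligned runs agreeing
#' with the final label.
#'
#' @param runs matrix (`n_runs x n_trials`) or list of labelings, all with the
#'   same k.
#' @return object of class `ConsensusResult`: `final_labels`, `stability`,
#'   `n_runs`.
#' @export
consensus_labels <- function(runs) {
  if (is.list(runs)) runs <- do.call(rbind, runs)
  stopifnot(is.matrix(runs), nrow(runs) >= 1)
  ks <- apply(runs, 1, function(r) length(unique(r)))
  if (length(unique(ks)) != 1) {
    stop("inconsistent cluster counts across runs: ",
         paste(unique(ks), collapse = ", "))
  }
  ref <- runs[1, ]
  aligned <- runs
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) aligned[i, ] <- align_labels(ref, runs[i, ])
  }
  k <- max(aligned)
  n <- ncol(aligned)
  final <- integer(n)
  stability <- numeric(n)
  for (j in seq_len(n)) {
    counts <- tabulate(aligned[, j], nbins = k)
    final[j] <- which.max(counts) # which.max takes the lowest index on ties
    stability[j] <- counts[final[j]] / nrow(aligned)
  }
  structure(list(final_labels = final, stability = stability,
                 n_runs = nrow(aligned)),
            class = "ConsensusResult")
}

#' Half-split reproducibility battery
#'
#' Per repeat: a random half of the trials is re-clustered from scratch
#' (consensus over `n_runs` embed+cluster runs at fixed `k`) and the aligned
#' label match ratio against the full-data reference labels (restricted to the
#' half) is recorded, together with per-cluster map similarities when maps are
#' supplied.
#'
#' @param maps list of `SpatialMap`s or matrix (rows = trials).
#' @param reference_labels full-data consensus labels.
#' @param k cluster count.
#' @param n_repeats half-split repetitions (default 100).
#' @param n_runs embed+cluster runs per half (default 10).
#' @param seed integer seed.
#' @param method embedding method.
#' @param n_neighbors embedding neighbor count (capped at half size - 1).
#' @return list with `match_ratios` (length `n_repeats`) and `map_similarity`
#'   (mean aligned per-cluster mean-map correlation per repeat).
#' @export
half_split_reproducibility <- function(maps, reference_labels, k,
                                       n_repeats = 100, n_runs = 10, seed = 1,
                                       method = "umap", n_neighbors = 7) {
  X <- maps_to_matrix(maps)
  n <- nrow(X)
  stopifnot(n >= 8, length(reference_labels) == n)
  ratios <- numeric(n_repeats)
  map_sim <- numeric(n_repeats)
  ref_means <- cluster_mean_rows(X, reference_labels, k)
  for (r in seq_len(n_repeats)) {
    half <- with_seed(substream_seed(seed, 7000L + r),
                      sort(sample.int(n, floor(n / 2))))
    Xh <- X[half, , drop = FALSE]
    runs <- matrix(NA_integer_, n_runs, length(half))
    for (b in seq_len(n_runs)) {
      emb <- embed_maps(Xh, n_neighbors = min(n_neighbors, nrow(Xh) - 1L),
                        seed = substream_seed(seed, r * 100L + b),
                        method = method)
      runs[b, ] <- fit_gmm(emb, k,
                           seed = substream_seed(seed, r * 100L + b))$labels
    }
    cons <- consensus_labels(runs)
    aligned <- align_labels(reference_labels[half], cons$final_labels)
    ratios[r] <- mean(aligned == reference_labels[half])
    hm <- cluster_mean_rows(Xh, aligned, k)
    sims <- vapply(seq_len(k), function(j) {
      if (any(is.na(hm[j, ])) || stats::sd(hm[j, ]) == 0) return(NA_real_)
      stats::cor(hm[j, ], ref_means[j, ])
    }, numeric(1))
    map_sim[r] <- mean(sims, na.rm = TRUE)
  }
  list(match_ratios = ratios, map_similarity = map_sim)
}

#' @keywords internal
#' @noRd
cluster_mean_rows <- function(X, labels, k) {
  out <- matrix(NA_real_, k, ncol(X))
  for (j in seq_len(k)) {
    rows <- labels == j
    if (any(rows)) out[j, ] <- colMeans(X[rows, , drop = FALSE])
  }
  out
}

#' Split trials into shorter temporal segments
#'
#' Each trial is cut into `floor(T * tr / segment_s)` non-overlapping segments
#' of `segment_s` seconds; the remainder is dropped. Segment metadata tracks
#' the parent trial.
#'
#' @param trials list of `Trial` objects.
#' @param segment_s segment duration in seconds (>= 60; must fit at least once
#'   in every trial).
#' @export
split_trials_temporally <- function(trials, segment_s) {
  stopifnot(segment_s >= 60)
  out <- list()
  for (tr in trials) {
    T_ <- ncol(tr$fmri)
    seg_frames <- floor(segment_s / tr$tr)
    n_seg <- floor(T_ / seg_frames)
    if (n_seg < 1) {
      stop("segment of ", segment_s, " s does not fit in trial ",
           tr$subject_id, " (", T_ * tr$tr, " s)")
    }
    for (s in seq_len(n_seg)) {
      idx <- ((s - 1) * seg_frames + 1):(s * seg_frames)
      seg <- new_trial(sprintf("%s_seg%02d", tr$subject_id, s),
                       tr$fmri[, idx, drop = FALSE], tr$pupil[idx], tr$tr,
                       tr$geometry)
      seg$parent <- tr$subject_id
      out[[length(out) + 1]] <- seg
    }
  }
  out
}
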