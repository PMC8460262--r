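# Voxel-wise pupil-fMRI correlation maps, map similarity, and spatial-
# autocorrelation-matched surrogate maps.

#' Spatial map constructor
#' @param values one value per in-mask voxel.
#' @param geometry a [generate_geometry()] object.
#' @param kind one of `"correlation"`, `"prediction"`, `"pvalue"`,
#'   `"surrogate"`.
#' @export
new_spatial_map <- function(values, geometry, kind = "correlation") {
  kind <- match.arg(kind, c("correlation", "prediction", "pvalue", "surrogate"))
  check_geometry(geometry)
  stopifnot(length(values) == geometry$n_voxels)
  if (kind == "correlation" && any(values < -1 - 1e-12 | values > 1 + 1e-12)) {
    stop("correlation map values must lie in [-1, 1]")
  }
  structure(list(values = as.numeric(values), geometry = geometry, kind = kind),
            class = "SpatialMap")
}

#' Voxel-wise Pearson correlation of fMRI with a pupil trace
#'
#' One Pearson r per voxel. Constant voxels (or a constant pupil trace) get
#' r = 0 and are counted in the `n_constant` attribute rather than dropped, so
#' map length is stable across trials.
#'
#' @param fmri `n_voxels x T` matrix or a `Trial`.
#' @param pupil length-`T` numeric (ignored when `fmri` is a `Trial`).
#' @param geometry required when `fmri` is a bare matrix.
#' @export
voxelwise_correlation <- function(fmri, pupil = NULL, geometry = NULL) {
  if (inherits(fmri, "Trial")) {
    geometry <- fmri$geometry
    pupil <- fmri$pupil
    fmri <- fmri$fmri
  }
  stopifnot(!is.null(geometry), ncol(fmri) == length(pupil), ncol(fmri) >= 3)
  r <- rowwise_pearson(fmri, pupil)
  nc <- attr(r, "n_constant")
  if (nc > 0) warning(nc, " constant voxel/pupil series set to r = 0")
  m <- new_spatial_map(pmin(1, pmax(-1, r)), geometry, "correlation")
  attr(m, "n_constant") <- nc
  m
}

#' All-trial correlation map from concatenated signals
#'
#' Per-trial fMRI voxel series and pupil traces are standardized, concatenated
#' along time, and correlated voxel-wise.
#'
#' @param trials list of `Trial` objects sharing one geometry.
#' @export
concatenated_map <- function(trials) {
  stopifnot(length(trials) >= 1)
  geom <- trials[[1]]$geometry
  for (tr in trials) {
    if (!identical(tr$geometry$shape, geom$shape) ||
        tr$geometry$n_voxels != geom$n_voxels) {
      stop("all trials must share one geometry")
    }
  }
  std <- function(m) {
    mc <- m - rowMeans(m)
    s <- sqrt(rowSums(mc^2) / (ncol(m) - 1))
    s[s == 0] <- 1
    mc / s
  }
  fmri <- do.call(cbind, lapply(trials, function(tr) std(tr$fmri)))
  pupil <- unlist(lapply(trials, function(tr) {
    s <- stats::sd(tr$pupil)
    if (s == 0) tr$pupil * 0 else (tr$pupil - mean(tr$pupil)) / s
  }))
  stopifnot(ncol(fmri) >= 3)
  voxelwise_correlation(fmri, pupil, geom)
}

#' Spatial similarity of two maps
#'
#' Pearson correlation over in-mask voxels; errors on constant maps.
#' @param a,b `SpatialMap` objects on the same geometry.
#' @export
spatial_similarity <- function(a, b) {
  stopifnot(inherits(a, "SpatialMap"), inherits(b, "SpatialMap"),
            length(a$values) == length(b$values))
  if (stats::sd(a$values) == 0 || stats::sd(b$values) == 0) {
    stop("spatial similarity undefined for a constant map")
  }
  stats::cor(a$values, b$values)
}

#' Empirical variogram of a spatial map
#'
#' Matheron estimator `gamma(h) = mean 0.5 (z_i - z_j)^2` over 25 equal-count
#' Euclidean-distance bins, on a seeded random subsample of at most
#' `max_pairs` voxel pairs.
#'
#' @param map a `SpatialMap`.
#' @param n_bins number of distance bins (default 25).
#' @param max_pairs pair subsample cap (default 50000).
#' @param seed subsampling seed.
#' @return data.frame with `distance` (bin mean) and `gamma`.
#' @export
map_variogram <- function(map, n_bins = 25, max_pairs = 50000, seed = 1) {
  stopifnot(inherits(map, "SpatialMap"))
  n <- length(map$values)
  if (n < 50) stop("map too small for variogram estimation (< 50 voxels)")
  co <- map$geometry$coords
  pairs <- with_seed(substream_seed(seed, 0L), {
    i <- sample.int(n, max_pairs, replace = TRUE)
    j <- sample.int(n, max_pairs, replace = TRUE)
    keep <- i != j
    cbind(i[keep], j[keep])
  })
  d <- sqrt(rowSums((co[pairs[, 1], , drop = FALSE] -
                       co[pairs[, 2], , drop = FALSE])^2))
  g <- 0.5 * (map$values[pairs[, 1]] - map$values[pairs[, 2]])^2
  qs <- stats::quantile(d, probs = seq(0, 1, length.out = n_bins + 1))
  bin <- cut(d, breaks = unique(qs), include.lowest = TRUE)
  data.frame(
    distance = as.numeric(tapply(d, bin, mean)),
    gamma = as.numeric(tapply(g, bin, mean))
  )
}

#' Variogram-matched surrogate maps
#'
#' Each surrogate keeps the original map's exact value multiset and
#' (approximately) its spatial autocorrelation while randomizing where values
#' sit. Values are randomly permuted, blended with a k-nearest-neighbor
#' smoothed copy of the permutation, and rank-remapped to the original value
#' multiset; the neighborhood size `k` and blend weight are fitted once per
#' input map to minimize the squared deviation from the target variogram.
#'
#' @param map a `SpatialMap` with >= 50 voxels.
#' @param n number of surrogates (default 100).
#' @param seed integer seed.
#' @param max_similarity reject (and re-draw) surrogates whose spatial
#'   correlation with the original exceeds this bound (default 0.8).
#' @param neighbors optional precomputed [surrogate_neighbors()] index matrix,
#'   reusable across maps sharing one geometry.
#' @return list of `SpatialMap` objects of kind `"surrogate"`.
#' @export
make_surrogates <- function(map, n = 100, seed = 1, max_similarity = 0.8,
                            neighbors = NULL) {
  stopifnot(inherits(map, "SpatialMap"), n >= 1)
  nv <- length(map$values)
  if (nv < 50) stop("map too small for surrogate generation (< 50 voxels)")
  target <- map_variogram(map, seed = seed)
  sorted_vals <- sort(map$values)
  k_grid <- unique(pmin(c(4L, 8L, 16L, 32L, 64L), nv - 1L))
  nb <- if (is.null(neighbors)) surrogate_neighbors(map$geometry) else neighbors
  stopifnot(nrow(nb) == nv, ncol(nb) >= max(k_grid))
  smooth_k <- function(x, k) rowMeans(matrix(x[nb[, seq_len(k)]], nv, k))
  build <- function(perm_vals, k, alpha) {
    y <- if (alpha > 0) {
      (1 - alpha) * perm_vals + alpha * smooth_k(perm_vals, k)
    } else {
      perm_vals
    }
    sorted_vals[rank(y, ties.method = "first")]
  }
  # fit (k, alpha) once on a pilot permutation; permutations are exchangeable
  pilot <- with_seed(substream_seed(seed, 1L), sample(map$values))
  best <- list(err = Inf, k = k_grid[1], alpha = 0)
  for (k in k_grid) {
    for (alpha in seq(0, 1, by = 0.1)) {
      cand <- new_spatial_map(build(pilot, k, alpha), map$geometry, "surrogate")
      vg <- map_variogram(cand, seed = seed)
      err <- sum((vg$gamma - target$gamma)^2)
      if (err < best$err) best <- list(err = err, k = k, alpha = alpha)
    }
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    for (attempt in 1:20) {
      pv <- with_seed(substream_seed(seed, 100L + i * 20L + attempt),
                      sample(map$values))
      cand <- new_spatial_map(build(pv, best$k, best$alpha),
                              map$geometry, "surrogate")
      if (abs(spatial_similarity(cand, map)) < max_similarity) break
    }
    out[[i]] <- cand
  }
  attr(out, "fit") <- best
  out
}

#' Nearest-neighbor index table for surrogate generation
#'
#' The `k = 64` nearest neighbors (excluding self) of every in-mask voxel;
#' compute once per geometry and pass to [make_surrogates()] when generating
#' surrogates for many maps.
#' @param geometry a [generate_geometry()] object.
#' @param k neighbors per voxel (default 64, the largest smoothing scale).
#' @export
surrogate_neighbors <- function(geometry, k = 64) {
  check_geometry(geometry)
  coords <- geometry$coords
  n <- nrow(coords)
  k <- min(k, n - 1L)
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  t(apply(d, 1, function(row) order(row)[seq_len(k)]))
}
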