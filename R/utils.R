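# Internal numeric helpers shared across modules.

#' @keywords internal
#' @noRd
substream_seed <- function(seed, index) {
  # Counter-based substream derivation: adding trials must not perturb earlier
  # ones, so every per-unit seed is a pure function of (seed, index).
  # All arithmetic kept well inside 2^53 so doubles are exact.
  s <- (as.double(seed) %% 2147483647) + 1
  i <- as.double(index) + 1
  h <- (s * 48271) %% 2147483647
  h <- (h + i * 69621) %% 2147483647
  h <- (h * 16807 + 12345) %% 2147483647
  as.integer(h)
}

#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' @keywords internal
#' @noRd
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("zero-variance input cannot be standardized")
  (x - mean(x)) / s
}

# Pearson correlation of each row of `m` (n x T) with vector `y` (length T).
# Zero-variance rows (or constant y) yield r = 0; count returned as attribute.
#' @keywords internal
#' @noRd
rowwise_pearson <- function(m, y) {
  stopifnot(ncol(m) == length(y))
  T_ <- length(y)
  yc <- y - mean(y)
  ys <- sqrt(sum(yc^2))
  mc <- m - rowMeans(m)
  ms <- sqrt(rowSums(mc^2))
  bad <- ms == 0 | ys == 0
  denom <- ms * ys
  denom[bad] <- 1
  r <- as.numeric(mc %*% yc) / denom
  r[bad] <- 0
  if (ys == 0) r[] <- 0
  attr(r, "n_constant") <- sum(ms == 0) + (ys == 0)
  r
}

#' @keywords internal
#' @noRd
pearson <- function(a, b) {
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(0)
  stats::cor(a, b)
}

# Zero-phase FFT low-pass: zeroes all bins strictly above `cutoff` Hz.
#' @keywords internal
#' @noRd
fft_lowpass <- function(x, dt, cutoff) {
  n <- length(x)
  f <- seq(0, n - 1) / (n * dt)
  f <- pmin(f, 1 / dt - f) # fold to [0, Nyquist]
  X <- stats::fft(x)
  X[f > cutoff] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

# Separable 3-D Gaussian smoothing of a full-grid array (FWHM in voxels).
# Kernel renormalized at edges so constants are preserved.
#' @keywords internal
#' @noRd
gaussian_smooth3d <- function(arr, fwhm) {
  if (fwhm <= 0) return(arr)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  rad <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-0.5 * ((-rad:rad) / sigma)^2)
  k <- k / sum(k)
  smooth_axis <- function(a, axis) {
    d <- dim(a)
    n <- d[axis]
    out <- array(0, d)
    wsum <- array(0, d)
    for (off in -rad:rad) {
      w <- k[off + rad + 1]
      src <- seq_len(n) + off
      ok <- src >= 1 & src <= n
      if (!any(ok)) next
      idx_dst <- which(ok)
      idx_src <- src[ok]
      if (axis == 1) {
        out[idx_dst, , ] <- out[idx_dst, , ] + w * a[idx_src, , ]
        wsum[idx_dst, , ] <- wsum[idx_dst, , ] + w
      } else if (axis == 2) {
        out[, idx_dst, ] <- out[, idx_dst, ] + w * a[, idx_src, ]
        wsum[, idx_dst, ] <- wsum[, idx_dst, ] + w
      } else {
        out[, , idx_dst] <- out[, , idx_dst] + w * a[, , idx_src]
        wsum[, , idx_dst] <- wsum[, , idx_dst] + w
      }
    }
    out / wsum
  }
  for (ax in 1:3) arr <- smooth_axis(arr, ax)
  arr
}

# All permutations of 1..n (n small; used for optimal label alignment, k <= 7).
#' @keywords internal
#' @noRd
permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (j in seq_len(nrow(sub))) {
      out[row, ] <- c(i, rest[sub[j, ]])
      row <- row + 1L
    }
  }
  out
}
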