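# Pupil trace construction and conditioning: landmark-to-diameter conversion,
# eye-size normalization, TR binning, HRF kernel family and convolution, and
# Welch power spectral density estimation.

#' Pupil trace constructor
#' @param values numeric diameter samples (unitless once normalized).
#' @param dt sampling interval, seconds (> 0).
#' @param normalized logical; TRUE when eye-size normalization has been
#'   applied, in which case all values must lie in \[0, 1\].
#' @export
new_pupil_trace <- function(values, dt, normalized = FALSE) {
  stopifnot(dt > 0, all(is.finite(values)))
  if (normalized && any(values < 0 | values > 1)) {
    stop("normalized pupil trace must lie in [0, 1]")
  }
  structure(list(values = as.numeric(values), dt = dt, normalized = normalized),
            class = "PupilTrace")
}

#' Pupil diameter from four tracked edge points
#'
#' Per frame the diameter is the mean of two chord lengths,
#' `d = (sqrt((x2-x1)^2 + (y2-y1)^2) + sqrt((x4-x3)^2 + (y4-y3)^2)) / 2`,
#' divided by the eye size so the result is a normalized diameter. Invariant
#' under global translation and rotation of the landmarks.
#'
#' @param series a `LandmarkSeries` (data.frame with `x1`..`y4` and attributes
#'   `fps`, `eye_size`), e.g. from [generate_landmark_track()] or
#'   [read_landmarks_csv()].
#' @return a [new_pupil_trace()] with `dt = 1/fps`, `normalized = TRUE`.
#' @export
diameter_from_landmarks <- function(series) {
  stopifnot(nrow(series) >= 1)
  eye <- attr(series, "eye_size")
  fps <- attr(series, "fps")
  stopifnot(!is.null(eye), eye > 0, !is.null(fps), fps > 0)
  c1 <- sqrt((series$x2 - series$x1)^2 + (series$y2 - series$y1)^2)
  c2 <- sqrt((series$x4 - series$x3)^2 + (series$y4 - series$y3)^2)
  d <- (c1 + c2) / 2 / eye
  new_pupil_trace(d, dt = 1 / fps, normalized = all(d >= 0 & d <= 1))
}

#' Average a trace into TR bins
#'
#' Non-overlapping windows of `round(tr / dt)` samples are averaged; a trailing
#' partial window is dropped, so the output length is deterministic.
#'
#' @param trace a `PupilTrace`.
#' @param tr target sampling interval (>= `trace$dt`).
#' @export
bin_to_tr <- function(trace, tr) {
  stopifnot(inherits(trace, "PupilTrace"), tr >= trace$dt)
  w <- round(tr / trace$dt)
  n_out <- floor(length(trace$values) / w)
  if (n_out < 1) stop("trace shorter than one ", tr, " s window")
  if (w == 1) {
    out <- trace$values[seq_len(n_out)]
  } else {
    m <- matrix(trace$values[seq_len(n_out * w)], nrow = w)
    out <- colMeans(m)
  }
  new_pupil_trace(out, dt = tr, normalized = trace$normalized)
}

#' Variance-normalize a series
#'
#' Centers to mean 0 and scales to variance 1 (the per-trial normalization
#' applied to both pupil traces and PCA component time courses before any
#' decoder sees them).
#'
#' @param values numeric vector, length >= 2.
#' @export
normalize_variance <- function(values) {
  stopifnot(length(values) >= 2)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) stop("zero-variance input cannot be normalized")
  (values - mean(values)) / s
}

#' Double-gamma hemodynamic response kernel
#'
#' `f(t) = t^(a-1) e^(-t) / Gamma(a) - 0.3 t^11 e^(-t) / Gamma(12)`, sampled at
#' `t = 0, dt, ..., length`, rescaled to unit peak. `a` controls the peak time
#' (larger `a`, later peak); the undershoot shape is fixed at 12 with weight
#' 0.3. Kernels with peaks anywhere in (0, 5] s are reachable for `a` in
#' roughly (1, 6].
#'
#' @param a shape parameter, must exceed 1 (at `a <= 1` the nominal peak sits
#'   on the t = 0 boundary).
#' @param dt sampling interval, seconds.
#' @param length_s kernel support in seconds (>= 20).
#' @return object of class `HRFKernel`: list with `a`, `dt`, `t`, `values`
#'   (unit peak), `peak_time`.
#' @export
hrf_kernel <- function(a, dt = 1, length_s = 30) {
  if (a <= 1) stop("a must be > 1 (peak would sit at the t = 0 boundary)")
  stopifnot(dt > 0, length_s >= 20)
  t <- seq(0, length_s, by = dt)
  v <- hrf_closed_form(t, a)
  pk <- max(v)
  stopifnot(is.finite(pk), pk > 0)
  structure(list(a = a, dt = dt, t = t, values = v / pk,
                 peak_time = t[which.max(v)]),
            class = "HRFKernel")
}

#' @keywords internal
#' @noRd
hrf_closed_form <- function(t, a) {
  t^(a - 1) * exp(-t) / gamma(a) - 0.3 * t^11 * exp(-t) / gamma(12)
}

#' Numeric peak time of the HRF closed form
#'
#' Dense-grid argmax of the (continuous) kernel; `solve_hrf_a()` inverts it.
#' @param a shape parameter (> 1).
#' @param dt grid step for the search (default 0.001 s).
#' @export
hrf_peak_time <- function(a, dt = 1e-3) {
  t <- seq(dt, 30, by = dt)
  t[which.max(hrf_closed_form(t, a))]
}

#' Shape parameter giving a desired HRF peak time
#' @param peak_s desired peak time in (0, 5\].
#' @export
solve_hrf_a <- function(peak_s) {
  stopifnot(peak_s > 0, peak_s <= 5)
  stats::uniroot(function(a) hrf_peak_time(a) - peak_s,
                 lower = 1 + 1e-4, upper = 8, tol = 1e-6)$root
}

#' Convolve a pupil trace with an HRF kernel
#'
#' Causal discrete convolution truncated to the input length, then re
#' variance-normalized (kernel amplitude is irrelevant downstream).
#'
#' @param trace a `PupilTrace`.
#' @param kernel an [hrf_kernel()]; `kernel$dt` must equal `trace$dt`.
#' @export
convolve_pupil <- function(trace, kernel) {
  stopifnot(inherits(trace, "PupilTrace"), inherits(kernel, "HRFKernel"))
  if (!isTRUE(all.equal(kernel$dt, trace$dt))) {
    stop("kernel dt (", kernel$dt, ") must match trace dt (", trace$dt, ")")
  }
  x <- trace$values
  full <- stats::convolve(x, rev(kernel$values), type = "open")
  y <- full[seq_along(x)]
  new_pupil_trace(normalize_variance(y), dt = trace$dt, normalized = FALSE)
}

#' Welch power spectral density
#'
#' 512-point DFT segments, Hann window, 50% overlap, constant detrend per
#' segment, one-sided density scaling. Series shorter than 512 samples are
#' handled as a single zero-padded segment.
#'
#' @param values numeric series (length >= 64, finite).
#' @param dt sampling interval in seconds.
#' @param nfft DFT length (default 512).
#' @return object of class `PSD`: list with `freqs` (Hz, starting at 0) and
#'   `power` (a.u.^2/Hz).
#' @export
welch_psd <- function(values, dt = 1, nfft = 512) {
  if (any(!is.finite(values))) stop("non-finite values in input series")
  n <- length(values)
  stopifnot(n >= 64)
  fs <- 1 / dt
  if (n >= nfft) {
    seg_len <- nfft
    hop <- nfft / 2
    starts <- seq(1, n - seg_len + 1, by = hop)
    pad <- 0L
  } else {
    seg_len <- n
    starts <- 1
    pad <- nfft - n
  }
  win <- hann_window(seg_len)
  u <- sum(win^2) # window power normalization
  acc <- numeric(nfft %/% 2 + 1)
  for (s in starts) {
    seg <- values[s:(s + seg_len - 1)]
    seg <- (seg - mean(seg)) * win
    if (pad > 0) seg <- c(seg, numeric(pad))
    sp <- stats::fft(seg)[seq_len(nfft %/% 2 + 1)]
    acc <- acc + (Mod(sp)^2) / (fs * u)
  }
  p <- acc / length(starts)
  # one-sided: double everything except DC and Nyquist
  inner <- 2:(length(p) - ifelse(nfft %% 2 == 0, 1, 0))
  p[inner] <- 2 * p[inner]
  freqs <- seq(0, nfft %/% 2) * fs / nfft
  structure(list(freqs = freqs, power = p, nfft = nfft, dt = dt),
            class = "PSD")
}

#' @keywords internal
#' @noRd
hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}
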