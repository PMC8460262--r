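# Synthetic cohort generator: latent spatial components, state-specific
# coupling to a pupil trace, and per-trial voxel x time matrices with known
# ground truth, emulating ~15-min trials at TR = 1 s (925 frames).

#' Generate latent spatial component maps
#'
#' Each component is a smoothed Gaussian random field plus a compact blob at a
#' randomly placed center, normalized to zero spatial mean and unit spatial
#' variance over in-mask voxels. Components play the role that PCA spatial
#' components play in real data: their time courses drive both the voxel
#' signals and the pupil trace.
#'
#' @param geom a [generate_geometry()] object.
#' @param K number of components (>= 1).
#' @param smoothness_fwhm Gaussian smoothing FWHM in voxels (0 = none).
#' @param seed integer seed.
#' @param max_overlap maximum allowed |pairwise spatial correlation| between
#'   distinct maps (default 0.3); placement is retried a bounded number of
#'   times before erroring.
#' @return object of class `ComponentAtlas`: list with `maps` (`K x n_voxels`),
#'   `K`, `geometry`.
#' @export
generate_component_maps <- function(geom, K, smoothness_fwhm = 2, seed = 1,
                                    max_overlap = 0.3) {
  check_geometry(geom)
  stopifnot(K >= 1, smoothness_fwhm >= 0)
  maps <- matrix(0, K, geom$n_voxels)
  max_retries <- 50L
  for (k in seq_len(K)) {
    placed <- FALSE
    for (attempt in seq_len(max_retries)) {
      m <- with_seed(substream_seed(seed, (k - 1L) * max_retries + attempt), {
        field <- array(stats::rnorm(prod(geom$shape)), geom$shape)
        ctr <- geom$coords[sample.int(geom$n_voxels, 1), ]
        blob_sigma <- max(geom$shape) / 8
        gx <- seq_len(geom$shape[1]); gy <- seq_len(geom$shape[2])
        gz <- seq_len(geom$shape[3])
        d2 <- outer(outer((gx - ctr[1])^2, (gy - ctr[2])^2, `+`),
                    (gz - ctr[3])^2, `+`)
        blob <- exp(-d2 / (2 * blob_sigma^2))
        sm <- gaussian_smooth3d(field, smoothness_fwhm)
        v <- (sm + 3 * blob * stats::sd(sm))[geom$mask]
        v <- v - mean(v)
        v / stats::sd(v)
      })
      ok <- TRUE
      if (k > 1) {
        cors <- abs(as.numeric(maps[seq_len(k - 1), , drop = FALSE] %*% m)) /
          (geom$n_voxels - 1)
        ok <- all(cors <= max_overlap)
      }
      if (ok) {
        maps[k, ] <- m
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place component ", k, " with pairwise |correlation| <= ",
           max_overlap, " after ", max_retries, " retries")
    }
  }
  structure(list(maps = maps, K = K, geometry = geom,
                 smoothness_fwhm = smoothness_fwhm, max_overlap = max_overlap),
            class = "ComponentAtlas")
}

#' Define a brain-state coupling profile
#'
#' A state is characterized by a K-vector of coupling weights mapping latent
#' component time courses to the pupil trace and by a state-specific ultra-slow
#' pupil oscillation frequency (the spectral signature that distinguishes
#' states in real recordings, e.g. peaks at 0.018 and 0.011 Hz).
#'
#' @param state_id integer label.
#' @param coupling numeric K-vector `w_k`; at least one entry must be nonzero.
#' @param oscillation_freq Hz; must lie in (0, Nyquist) for the cohort's TR.
#' @export
state_profile <- function(state_id, coupling, oscillation_freq) {
  stopifnot(length(coupling) >= 1, any(coupling != 0), oscillation_freq > 0)
  structure(list(state_id = as.integer(state_id),
                 coupling = as.numeric(coupling),
                 oscillation_freq = oscillation_freq),
            class = "StateProfile")
}

#' Default four-state profiles
#'
#' Four states over K = 6 components with distinct coupling vectors and
#' spectral peaks (0.018, 0.008, 0.006, 0.011 Hz), mirroring a cohort in which
#' one state has a distinct ~0.018 Hz pupil rhythm, two sit below 0.01 Hz and
#' one peaks at 0.011 Hz.
#' @param K number of latent components (>= 4; base weights are defined over
#'   six components and truncated or zero-padded to K, every state keeping at
#'   least one nonzero weight).
#' @export
default_state_profiles <- function(K = 6) {
  stopifnot(K >= 4)
  pad <- function(w) if (K >= 6) c(w, rep(0, K - 6)) else w[seq_len(K)]
  list(
    state_profile(1L, pad(c(1, 0.5, 0, 0, 0, 0)), 0.018),
    state_profile(2L, pad(c(0, 0, 1, 0.5, 0, 0)), 0.008),
    state_profile(3L, pad(c(0, 0.6, 0, 0, -1, 0)), 0.006),
    state_profile(4L, pad(c(0.5, 0, 0, -0.5, 0, 1)), 0.011)
  )
}

# Band-limited smooth noise: white noise low-passed below `cutoff` Hz
# (zero-phase), then variance-normalized.
#' @keywords internal
#' @noRd
latent_timecourse <- function(T_, dt, cutoff = 0.1) {
  x <- fft_lowpass(stats::rnorm(T_), dt, cutoff)
  zscore(x)
}

#' Generate a synthetic cohort with planted brain states
#'
#' Per trial, K latent time courses `s_k(t)` are band-limited smooth noise
#' (white noise low-passed below 0.1 Hz, zero-phase, variance-normalized);
#' components with nonzero coupling weight additionally carry a sinusoid at
#' the state's oscillation frequency (amplitude `osc_amplitude`, random phase).
#' Voxel signals are `fmri(v,t) = sum_k C_k(v) s_k(t) + eps(v,t)` and the pupil
#' trace is `pupil(t) = sum_k w_k s_k(t - lag) + eta(t)`, with independent
#' Gaussian noise. Each trial draws from its own counter-based RNG substream,
#' so extending the cohort never perturbs earlier trials.
#'
#' @param geom,atlas geometry and component atlas (see
#'   [generate_component_maps()]).
#' @param profiles list of [state_profile()] objects.
#' @param n_trials_per_state integer vector, one count per profile.
#' @param T_frames frames per trial (default 925, i.e. ~15 min at TR = 1 s).
#' @param tr sampling interval in seconds (default 1).
#' @param noise_sd_fmri,noise_sd_pupil additive Gaussian noise SDs.
#' @param osc_amplitude amplitude of the state sinusoid (default 1).
#' @param pupil_lag_frames integer lag of the pupil behind the latents
#'   (default 0); used to plant a known shift for shift-sweep tests.
#' @param seed integer seed.
#' @return list with `trials` (list of `Trial`) and `ground_truth`
#'   (`GroundTruth`: atlas, per-trial state labels, latent time courses, noise
#'   realizations and parameters, sufficient to reconstruct every pupil trace
#'   bit-exactly).
#' @export
generate_cohort <- function(geom, atlas, profiles, n_trials_per_state,
                            T_frames = 925, tr = 1,
                            noise_sd_fmri = 1.0, noise_sd_pupil = 0.3,
                            osc_amplitude = 1.0, pupil_lag_frames = 0L,
                            seed = 1) {
  check_geometry(geom)
  stopifnot(inherits(atlas, "ComponentAtlas"),
            length(profiles) == length(n_trials_per_state),
            T_frames >= 64, tr > 0,
            noise_sd_fmri >= 0, noise_sd_pupil >= 0)
  nyquist <- 1 / (2 * tr)
  for (p in profiles) {
    stopifnot(inherits(p, "StateProfile"), length(p$coupling) == atlas$K)
    if (p$oscillation_freq >= nyquist) {
      stop("oscillation_freq ", p$oscillation_freq,
           " Hz is at or above Nyquist (", nyquist, " Hz)")
    }
  }
  pupil_lag_frames <- as.integer(pupil_lag_frames)
  K <- atlas$K
  trials <- list()
  state_labels <- integer(0)
  latents <- list()
  etas <- list()
  trial_idx <- 0L
  for (s in seq_along(profiles)) {
    prof <- profiles[[s]]
    for (j in seq_len(n_trials_per_state[s])) {
      trial_idx <- trial_idx + 1L
      tseed <- substream_seed(seed, trial_idx)
      gen <- with_seed(tseed, {
        S <- matrix(0, K, T_frames)
        tgrid <- (seq_len(T_frames) - 1) * tr
        for (k in seq_len(K)) {
          S[k, ] <- latent_timecourse(T_frames, tr)
          if (prof$coupling[k] != 0) {
            phase <- stats::runif(1, 0, 2 * pi)
            S[k, ] <- S[k, ] +
              osc_amplitude * sin(2 * pi * prof$oscillation_freq * tgrid + phase)
          }
        }
        eps <- if (noise_sd_fmri > 0) {
          matrix(stats::rnorm(geom$n_voxels * T_frames, sd = noise_sd_fmri),
                 geom$n_voxels, T_frames)
        } else {
          matrix(0, geom$n_voxels, T_frames)
        }
        eta <- if (noise_sd_pupil > 0) {
          stats::rnorm(T_frames, sd = noise_sd_pupil)
        } else {
          rep(0, T_frames)
        }
        list(S = S, eps = eps, eta = eta)
      })
      drive <- as.numeric(prof$coupling %*% gen$S)
      if (pupil_lag_frames != 0) {
        # pupil(t) = drive(t - lag); edges wrap so every trial keeps length T.
        idx <- ((seq_len(T_frames) - 1 - pupil_lag_frames) %% T_frames) + 1
        drive <- drive[idx]
      }
      fmri <- crossprod(atlas$maps, gen$S) + gen$eps # n_voxels x T
      pupil <- drive + gen$eta
      trials[[trial_idx]] <- new_trial(
        subject_id = sprintf("synth%02d", trial_idx),
        fmri = fmri, pupil = pupil, tr = tr, geometry = geom
      )
      state_labels[trial_idx] <- prof$state_id
      latents[[trial_idx]] <- gen$S
      etas[[trial_idx]] <- gen$eta
    }
  }
  gt <- structure(
    list(atlas = atlas, profiles = profiles, state_labels = state_labels,
         latent_timecourses = latents, pupil_noise = etas,
         noise_sd_fmri = noise_sd_fmri, noise_sd_pupil = noise_sd_pupil,
         osc_amplitude = osc_amplitude, pupil_lag_frames = pupil_lag_frames,
         seed = seed),
    class = "GroundTruth"
  )
  list(trials = trials, ground_truth = gt)
}

#' Trial constructor
#'
#' @param subject_id label.
#' @param fmri `n_voxels x T` matrix (arbitrary units).
#' @param pupil length-`T` trace.
#' @param tr seconds (> 0).
#' @param geometry optional [generate_geometry()] object.
#' @export
new_trial <- function(subject_id, fmri, pupil, tr, geometry = NULL) {
  fmri <- as.matrix(fmri)
  stopifnot(ncol(fmri) == length(pupil), tr > 0,
            all(is.finite(fmri)), all(is.finite(pupil)))
  if (!is.null(geometry)) stopifnot(nrow(fmri) == geometry$n_voxels)
  structure(list(subject_id = subject_id, fmri = fmri,
                 pupil = as.numeric(pupil), tr = tr, geometry = geometry),
            class = "Trial")
}

#' @export
print.Trial <- function(x, ...) {
  cat(sprintf("Trial %s: %d voxels x %d frames, TR = %g s\n",
              x$subject_id, nrow(x$fmri), ncol(x$fmri), x$tr))
  invisible(x)
}

#' Reconstruct a trial's pupil trace from the ground truth
#'
#' Bookkeeping invariant of the generator: the coupling-weighted sum of the
#' stored latent time courses (lagged as generated) plus the stored noise
#' realization reproduces the trial's pupil trace bit-exactly.
#' @param gt a `GroundTruth`.
#' @param i trial index.
#' @export
reconstruct_pupil <- function(gt, i) {
  prof <- NULL
  for (p in gt$profiles) if (p$state_id == gt$state_labels[i]) prof <- p
  drive <- as.numeric(prof$coupling %*% gt$latent_timecourses[[i]])
  T_ <- length(drive)
  if (gt$pupil_lag_frames != 0) {
    idx <- ((seq_len(T_) - 1 - gt$pupil_lag_frames) %% T_) + 1
    drive <- drive[idx]
  }
  drive + gt$pupil_noise[[i]]
}

#' Simulate landmark tracking of a pupil video
#'
#' Emits per-frame coordinates of four pupil edge points (two horizontal and
#' two vertical chord endpoints) such that the diameter formula
#' ([diameter_from_landmarks()]) followed by eye-size normalization and TR
#' binning ([bin_to_tr()]) recovers the trial's pupil trace. Frames are laid
#' out in blocks of `round(tr * fps)` per TR bin, each frame carrying its
#' bin's diameter, so the round trip is exact up to floating point for
#' noise-free placement.
#'
#' @param trial a `Trial` whose pupil values lie in (0, 1] (normalized
#'   diameter).
#' @param eye_size eye size in pixels (> 0) used for normalization.
#' @param fps camera frame rate (default 29.97 Hz, >= 1/tr).
#' @param seed seed for the per-frame rigid jitter (translation + rotation),
#'   which the diameter formula is invariant to.
#' @param jitter_px SD of the random rigid translation (default 0, exact).
#' @return object of class `LandmarkSeries`: data.frame with columns `frame`,
#'   `x1`..`y4`, plus attributes `fps`, `eye_size`.
#' @export
generate_landmark_track <- function(trial, eye_size = 100, fps = 29.97,
                                    seed = 1, jitter_px = 0) {
  stopifnot(inherits(trial, "Trial"), eye_size > 0, fps >= 1 / trial$tr)
  p <- trial$pupil
  if (any(p <= 0 | p > 1)) {
    stop("trial pupil values must lie in (0, 1] to be rendered as landmarks; ",
         "rescale the trace first")
  }
  per_bin <- round(trial$tr * fps)
  T_ <- length(p)
  n_frames <- per_bin * T_
  d_px <- rep(p, each = per_bin) * eye_size # per-frame chord length, pixels
  base <- with_seed(substream_seed(seed, 0L), {
    ang <- stats::runif(n_frames, 0, 2 * pi)
    ox <- if (jitter_px > 0) stats::rnorm(n_frames, sd = jitter_px) else rep(0, n_frames)
    oy <- if (jitter_px > 0) stats::rnorm(n_frames, sd = jitter_px) else rep(0, n_frames)
    list(ang = ang, ox = ox, oy = oy)
  })
  r <- d_px / 2
  ca <- cos(base$ang); sa <- sin(base$ang)
  # chord 1 endpoints along the rotated x-axis, chord 2 along the y-axis
  df <- data.frame(
    frame = seq_len(n_frames),
    x1 = base$ox - r * ca, y1 = base$oy - r * sa,
    x2 = base$ox + r * ca, y2 = base$oy + r * sa,
    x3 = base$ox + r * sa, y3 = base$oy - r * ca,
    x4 = base$ox - r * sa, y4 = base$oy + r * ca
  )
  structure(df, fps = fps, eye_size = eye_size, class = c("LandmarkSeries", "data.frame"))
}
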