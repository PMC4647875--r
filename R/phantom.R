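#' Configuration for the synthetic R2* phantom
#'
#' Defines the study conditions the phantom emulates: a ~60-min dynamic
#' acquisition at 3.8 s per frame (947 frames), an ellipsoidal tumour inside a
#' 32 x 32 x 5 grid, a slow systemic oscillation shared with the O2sat trace,
#' spatially clustered tumour-specific oscillators below 1e-3 Hz, and
#' broadband Gaussian noise. Defaults put both signal classes at amplitude
#' ~3x the noise s.d. so that each is detectable but not trivial.
#'
#' The systemic signal enters with a negative sign (O2sat up implies
#' deoxyhaemoglobin down implies R2* down); classification is sign-agnostic.
#'
#' @param grid_shape Integer length-3, (x, y, z) grid size.
#' @param frame_interval Seconds per frame.
#' @param n_frames Number of frames (default `floor(3600 / 3.8)` = 947).
#' @param baseline_r2star Baseline R2* in ms^-1 added to every in-mask voxel.
#' @param mask_semiaxes Ellipsoid semi-axes of the tumour mask, in voxels.
#' @param f_systemic Systemic oscillation frequency, Hz.
#' @param systemic_amplitude R2* amplitude (ms^-1) of a unit-gain systemic
#'   voxel; per-voxel gains are drawn uniformly from `systemic_gain_range`.
#' @param systemic_coverage Fraction of in-mask voxels that receive systemic
#'   signal; 0 disables the systemic class.
#' @param systemic_region `"random"` (default): systemic voxels are drawn
#'   voxel-wise iid, making the systemic map spatially independent of the
#'   cluster maps — the identifiability assumption of spatial ICA. Any
#'   spatially contiguous region is intrinsically correlated with a compact
#'   cluster map (the cluster lies wholly inside or outside it), which
#'   biases *any* ICA rotation in proportion to that correlation times the
#'   class energy ratio. `"left"`: a contiguous region covering the lowest
#'   `systemic_coverage` fraction of the tumour's x-extent, for
#'   geometry-driven demonstrations.
#' @param systemic_gain_dist Distribution of the per-voxel systemic gain:
#'   `"exp"` (default) draws unit-mean exponential gains — a right-skewed,
#'   sparse-positive participation map, as a vascular-density-like weighting
#'   would give, and a heavy-tailed (super-Gaussian) source for which the
#'   logcosh FastICA contrast is uniformly stable; `"uniform"` draws from
#'   `systemic_gain_range`.
#' @param systemic_gain_range Range of the per-voxel systemic gain for
#'   `systemic_gain_dist = "uniform"`.
#' @param clusters Data frame of tumour-specific oscillator clusters with
#'   columns `x, y, z, radius, amplitude` (voxel units; amplitude in ms^-1),
#'   or `NULL` for none. Each cluster oscillates coherently with its own
#'   random phase.
#' @param tumour_frequencies Frequencies (Hz) of the cluster oscillators,
#'   recycled across clusters.
#' @param noise_sd Gaussian noise s.d. (ms^-1) added to every in-mask voxel.
#' @param o2sat_baseline,o2sat_excursion O2sat baseline and sinusoidal
#'   amplitude, percent.
#' @param o2sat_noise_sd,o2sat_ar AR(1) noise s.d. (percent) and coefficient
#'   of the oximetry trace.
#' @param o2sat_rate_hz Oximeter sampling rate, Hz.
#' @param seed Integer seed fixing all randomness.
#' @return A validated list of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(32L, 32L, 5L),
                           frame_interval = 3.8,
                           n_frames = 947L,
                           baseline_r2star = 0.12,
                           mask_semiaxes = c(12, 12, 2.2),
                           f_systemic = NULL,
                           systemic_amplitude = 0.004,
                           systemic_coverage = 0.5,
                           systemic_region = c("random", "left"),
                           systemic_gain_dist = c("exp", "uniform"),
                           systemic_gain_range = c(0.5, 1.5),
                           clusters = default_clusters(),
                           tumour_frequencies = NULL,
                           noise_sd = 0.002,
                           o2sat_baseline = 95,
                           o2sat_excursion = 3,
                           o2sat_noise_sd = 0.3,
                           o2sat_ar = 0.9,
                           o2sat_rate_hz = 1,
                           seed = 1L) {
  # default injected frequencies sit on the acquisition's DFT grid
  # (bins 2 and 3: ~5.56e-4 and ~8.34e-4 Hz for 947 frames at 3.8 s), so the
  # injected sources are exactly orthogonal over the finite window. Off-grid
  # sinusoids at these sub-mHz separations leak into one another at the
  # |r| ~ 0.08 level over an hour-long window, which is precisely the
  # detection boundary of a p < 0.01 correlation test at ~950 frames; a
  # ground-truth phantom must not have that ambiguity built in.
  if (is.null(f_systemic))
    f_systemic <- 2 / (n_frames * frame_interval)
  if (is.null(tumour_frequencies))
    tumour_frequencies <- 3 / (n_frames * frame_interval)
  cfg <- list(grid_shape = as.integer(grid_shape), frame_interval = frame_interval,
              n_frames = as.integer(n_frames), baseline_r2star = baseline_r2star,
              mask_semiaxes = mask_semiaxes, f_systemic = f_systemic,
              systemic_amplitude = systemic_amplitude,
              systemic_coverage = systemic_coverage,
              systemic_region = match.arg(systemic_region),
              systemic_gain_dist = match.arg(systemic_gain_dist),
              systemic_gain_range = systemic_gain_range,
              clusters = clusters, tumour_frequencies = tumour_frequencies,
              noise_sd = noise_sd, o2sat_baseline = o2sat_baseline,
              o2sat_excursion = o2sat_excursion, o2sat_noise_sd = o2sat_noise_sd,
              o2sat_ar = o2sat_ar, o2sat_rate_hz = o2sat_rate_hz,
              seed = as.integer(seed))
  nyq <- 1 / (2 * cfg$frame_interval)
  if (cfg$f_systemic >= nyq || any(cfg$tumour_frequencies >= nyq))
    stop("all injected frequencies must be below Nyquist = ",
         signif(nyq, 3), " Hz", call. = FALSE)
  if (cfg$systemic_amplitude < 0 || cfg$noise_sd < 0 || cfg$o2sat_excursion < 0)
    stop("amplitudes must be >= 0", call. = FALSE)
  if (!is.null(cfg$clusters)) {
    need <- c("x", "y", "z", "radius", "amplitude")
    if (!all(need %in% names(cfg$clusters)))
      stop("`clusters` needs columns ", paste(need, collapse = ", "), call. = FALSE)
    if (any(cfg$clusters$amplitude < 0)) stop("cluster amplitudes must be >= 0", call. = FALSE)
  }
  structure(cfg, class = "phantom_config")
}

#' Default tumour-specific oscillator cluster
#'
#' One radius-3 spherical cluster in the right (non-systemic) half of the
#' tumour. A single cluster per injected frequency keeps the phantom
#' identifiable: two clusters sharing one frequency differ only by phase,
#' and when the drawn phases nearly coincide their temporal sources are
#' collinear, so only the sum of their maps is recoverable by any
#' decomposition. Overlapping systemic/tumour-specific signal is exercised
#' by configuring a cluster inside the systemic region.
#'
#' @return A tibble with columns `x, y, z, radius, amplitude`.
#' @export
default_clusters <- function() {
  tibble::tibble(x = 22, y = 16, z = 3, radius = 3, amplitude = 0.01)
}

#' Generate a synthetic O2sat trace
#'
#' Baseline plus a slow sinusoid at the systemic frequency plus AR(1) noise,
#' sampled at the oximeter rate and clipped to \[0, 100\]. Deterministic under
#' the config seed.
#'
#' @param config A [phantom_config()].
#' @return An [o2sat_trace()].
#' @export
generate_o2sat_trace <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  total <- config$n_frames * config$frame_interval
  times <- seq(0, ceiling(total), by = 1 / config$o2sat_rate_hz)
  clean <- config$o2sat_baseline +
    config$o2sat_excursion * sin(2 * pi * config$f_systemic * times)
  n <- length(times)
  noise <- numeric(n)
  if (config$o2sat_noise_sd > 0) {
    innov_sd <- config$o2sat_noise_sd * sqrt(1 - config$o2sat_ar^2)
    noise[1] <- rnorm(1, sd = config$o2sat_noise_sd)
    for (i in seq_len(n - 1L))
      noise[i + 1L] <- config$o2sat_ar * noise[i] + rnorm(1, sd = innov_sd)
  }
  v <- clean + noise
  if (any(v < -5) || any(v > 105))
    warning("O2sat values exceed [0, 100] by > 5 percentage points before clipping",
            call. = FALSE)
  o2sat_trace(times, pmin(100, pmax(0, v)))
}

#' Generate a synthetic R2* phantom with ground truth
#'
#' Builds an ellipsoidal tumour inside the configured grid and injects, on
#' top of the R2* baseline and Gaussian noise: (i) a systemic fluctuation,
#' the standardised O2sat trace resampled to frame midpoints, applied with
#' negative sign and a per-voxel gain over the systemic region; and (ii)
#' coherent sinusoids with random phase in each tumour-specific cluster.
#' Ground-truth label maps record exactly the voxels with nonzero injected
#' amplitude for each class; a voxel may carry both classes.
#'
#' @param config A [phantom_config()].
#' @return A list of class `synthetic_dataset`: `series` ([r2star_series()]),
#'   `o2sat` ([o2sat_trace()]), logical maps `truth_systemic` and
#'   `truth_tumour_specific`, and `params` (config plus drawn gains/phases).
#' @examples
#' cfg <- phantom_config(grid_shape = c(12, 12, 3), n_frames = 60,
#'                       mask_semiaxes = c(5, 5, 1.4),
#'                       clusters = data.frame(x = 8, y = 6, z = 2,
#'                                             radius = 1.5, amplitude = 0.006))
#' ph <- generate_phantom(cfg)
#' ph$series
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  o2 <- generate_o2sat_trace(config)  # seeds the RNG with config$seed
  g <- config$grid_shape
  centre <- (g + 1) / 2
  ax <- expand.grid(x = seq_len(g[1]), y = seq_len(g[2]), z = seq_len(g[3]))
  rad2 <- ((ax$x - centre[1]) / config$mask_semiaxes[1])^2 +
    ((ax$y - centre[2]) / config$mask_semiaxes[2])^2 +
    ((ax$z - centre[3]) / config$mask_semiaxes[3])^2
  mask <- array(rad2 <= 1, g)
  if (!any(mask)) stop("mask is empty; enlarge `mask_semiaxes`", call. = FALSE)

  nvox <- sum(mask)
  tmid <- frame_midpoints(config$n_frames, config$frame_interval)
  Tn <- config$n_frames

  # systemic temporal source: standardised interpolated O2sat
  s_sys <- o2sat_at_frames(o2, Tn, config$frame_interval)
  s_sys <- if (sd(s_sys) > 0) (s_sys - mean(s_sys)) / sd(s_sys) else s_sys * 0

  sys_vox <- rep(FALSE, nvox)
  if (config$systemic_coverage > 0 && config$systemic_amplitude > 0) {
    if (config$systemic_region == "random") {
      sys_vox <- runif(nvox) < config$systemic_coverage
    } else {
      xs <- ax$x[as.vector(mask)]
      xcut <- min(xs) + config$systemic_coverage * (max(xs) - min(xs))
      sys_vox <- xs <= xcut
    }
  }
  gains <- numeric(nvox)
  gains[sys_vox] <- if (config$systemic_gain_dist == "exp")
    stats::rexp(sum(sys_vox)) else
    runif(sum(sys_vox), config$systemic_gain_range[1],
          config$systemic_gain_range[2])

  # in-mask signal matrix, frames x voxels
  X <- matrix(rnorm(Tn * nvox, sd = config$noise_sd), Tn, nvox)
  X <- X + config$baseline_r2star
  X <- X - config$systemic_amplitude * outer(s_sys, gains)

  tsp_vox <- rep(FALSE, nvox)
  phases <- numeric(0)
  if (!is.null(config$clusters) && nrow(config$clusters) > 0) {
    cl <- config$clusters
    freqs <- rep_len(config$tumour_frequencies, nrow(cl))
    phases <- runif(nrow(cl), 0, 2 * pi)
    coords <- ax[as.vector(mask), ]
    for (i in seq_len(nrow(cl))) {
      inball <- (coords$x - cl$x[i])^2 + (coords$y - cl$y[i])^2 +
        (coords$z - cl$z[i])^2 <= cl$radius[i]^2
      if (!any(inball))
        stop("cluster ", i, " lies outside the tumour mask", call. = FALSE)
      if (cl$amplitude[i] > 0) {
        tsp_vox <- tsp_vox | inball
        X[, inball] <- X[, inball] +
          cl$amplitude[i] * sin(2 * pi * freqs[i] * tmid + phases[i])
      }
    }
  }

  vol <- array(0, c(g, Tn))
  flat <- matrix(vol, prod(g), Tn)
  flat[as.vector(mask), ] <- t(X)
  vol <- array(flat, c(g, Tn))

  truth_sys <- array(FALSE, g); truth_sys[mask] <- sys_vox & gains > 0
  truth_tsp <- array(FALSE, g); truth_tsp[mask] <- tsp_vox

  structure(
    list(series = r2star_series(vol, config$frame_interval, mask = mask),
         o2sat = o2,
         truth_systemic = truth_sys,
         truth_tumour_specific = truth_tsp,
         params = c(unclass(config),
                    list(gains = gains, cluster_phases = phases))),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset>\n")
  print(x$series)
  cat(sprintf("  truth: %d systemic, %d tumour-specific voxels (%d overlap)\n",
              sum(x$truth_systemic), sum(x$truth_tumour_specific),
              sum(x$truth_systemic & x$truth_tumour_specific)))
  invisible(x)
}
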