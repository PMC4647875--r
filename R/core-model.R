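#' Voxel-wise R2* time series
#'
#' Container for a dynamic R2* acquisition: a 4D grid of effective transverse
#' relaxation rates (R2* = 1/T2*, in ms^-1) over time, together with a tumour
#' mask and the frame interval. R2* increases with local deoxyhaemoglobin
#' concentration, so its temporal fluctuations carry the blood-oxygenation
#' dynamics that the decomposition pipeline separates into systemic and
#' tumour-specific sources.
#'
#' Arrays are stored in R's column-major convention with axes (x, y, z, time);
#' voxel indices are 1-based. The in-mask voxel order used by every matrix
#' operation in the package is the column-major order of `which(mask)`.
#'
#' @param values 4D numeric array, dimensions (x, y, z, time), R2* in ms^-1.
#' @param frame_interval Seconds per frame (> 0).
#' @param mask Logical 3D array marking tumour voxels; defaults to all voxels.
#' @param voxel_size Optional numeric length-3, voxel edge lengths in mm.
#'
#' @return An object of class `r2star_series`.
#' @examples
#' arr <- array(rnorm(4 * 4 * 2 * 10, mean = 0.1, sd = 0.01), c(4, 4, 2, 10))
#' ser <- r2star_series(arr, frame_interval = 3.8)
#' ser
#' @export
r2star_series <- function(values, frame_interval, mask = NULL, voxel_size = NULL) {
  if (!is.array(values) || length(dim(values)) != 4L)
    stop("`values` must be a 4D array with axes (x, y, z, time)", call. = FALSE)
  d <- dim(values)
  if (d[4] < 2L) stop("time dimension must have length >= 2", call. = FALSE)
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      !is.finite(frame_interval) || frame_interval <= 0)
    stop("`frame_interval` must be a single positive number (seconds)", call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  mask <- array(as.logical(mask), dim(mask))
  if (!identical(dim(mask), d[1:3]))
    stop("`mask` dimensions must match the spatial dimensions of `values`", call. = FALSE)
  if (!any(mask)) stop("`mask` must contain at least one voxel", call. = FALSE)
  if (anyNA(mask)) stop("`mask` must not contain NA", call. = FALSE)
  vm <- matrix(values, prod(d[1:3]), d[4])[as.vector(mask), , drop = FALSE]
  if (!all(is.finite(vm)))
    stop("all in-mask R2* values must be finite", call. = FALSE)
  structure(
    list(values = values, frame_interval = frame_interval,
         mask = mask, voxel_size = voxel_size),
    class = "r2star_series"
  )
}

#' @export
print.r2star_series <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<r2star_series> %d x %d x %d grid, %d frames @ %.3g s (%.1f min)\n",
              d[1], d[2], d[3], d[4], x$frame_interval,
              d[4] * x$frame_interval / 60))
  cat(sprintf("  mask: %d voxels; in-mask mean R2* %.4g ms^-1\n",
              sum(x$mask), mean(series_matrix(x))))
  invisible(x)
}

#' Extract the in-mask data matrix
#'
#' Returns the time-by-voxel matrix X whose columns are the in-mask voxel
#' time-courses (column-major voxel order of `which(mask)`). This is the matrix
#' that PCA and spatial ICA decompose.
#'
#' @param series An [r2star_series()].
#' @return Numeric matrix, frames x in-mask voxels.
#' @export
series_matrix <- function(series) {
  stopifnot(inherits(series, "r2star_series"))
  d <- dim(series$values)
  t(matrix(series$values, prod(d[1:3]), d[4])[as.vector(series$mask), , drop = FALSE])
}

#' Frame midpoint times
#'
#' Times (seconds from acquisition start) at the midpoint of each frame,
#' used when aligning the pulse-oximetry trace to the MRI frames.
#'
#' @param n_frames Number of frames.
#' @param frame_interval Seconds per frame.
#' @return Numeric vector of length `n_frames`.
#' @export
frame_midpoints <- function(n_frames, frame_interval) {
  (seq_len(n_frames) - 0.5) * frame_interval
}

#' Estimate R2* from multi-echo gradient-echo magnitudes
#'
#' Log-linear ordinary least squares: the mono-exponential decay
#' S(TE) = S0 exp(-R2* TE) implies -log S is linear in TE with slope R2*.
#' The estimate is the OLS slope; it can be negative for noisy input, in
#' which case a warning flags it. A single-echo dynamic series can instead be
#' supplied directly to [r2star_series()] as an R2*-proxy.
#'
#' @param echo_times Echo times in ms, strictly increasing, length >= 2.
#' @param signals Positive magnitudes: a vector (one decay) or a matrix with
#'   one row per echo and one column per voxel.
#' @return R2* in ms^-1: a scalar, or one value per column of `signals`.
#' @examples
#' te <- c(1, 3, 5, 7)
#' estimate_r2star(te, 100 * exp(-0.12 * te))
#' @export
estimate_r2star <- function(echo_times, signals) {
  if (length(echo_times) < 2L) stop("need at least 2 echoes", call. = FALSE)
  if (is.unsorted(echo_times, strictly = TRUE))
    stop("`echo_times` must be strictly increasing", call. = FALSE)
  s <- if (is.matrix(signals)) signals else matrix(signals, ncol = 1L)
  if (nrow(s) != length(echo_times))
    stop("`signals` must have one value per echo", call. = FALSE)
  if (any(!is.finite(s)) || any(s <= 0))
    stop("all signals must be positive and finite (log-linear fit)", call. = FALSE)
  te <- echo_times - mean(echo_times)
  slope <- as.vector(crossprod(te, -log(s))) / sum(te^2)
  if (any(slope < 0))
    warning("negative R2* estimate(s): noisy or non-decaying input", call. = FALSE)
  if (is.matrix(signals)) slope else slope[1L]
}

#' Per-voxel summary map
#'
#' 3D map of a per-voxel scalar defined on the tumour mask (NA elsewhere),
#' e.g. the temporal standard deviation of the R2* fluctuations.
#'
#' @param values 3D numeric array, NA outside the mask.
#' @param mask Logical 3D array.
#' @param label Character tag for the map kind.
#' @return An object of class `summary_map`.
#' @export
summary_map <- function(values, mask, label = "map") {
  stopifnot(is.array(values), length(dim(values)) == 3L,
            identical(dim(values), dim(mask)))
  structure(list(values = values, mask = mask, label = label),
            class = "summary_map")
}

#' @export
print.summary_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<summary_map: %s> %s grid, %d mask voxels, range [%.4g, %.4g]\n",
              x$label, paste(dim(x$values), collapse = " x "),
              sum(x$mask), min(v), max(v)))
  invisible(x)
}

#' Temporal standard deviation map
#'
#' Per in-mask voxel, the sample standard deviation (divisor n - 1) of its
#' R2* time-course. High values mark voxels with large spontaneous
#' fluctuations; the map is the standard first-look display of a dynamic
#' acquisition.
#'
#' @param series An [r2star_series()].
#' @return A [summary_map()] labelled `"temporal_sd"`.
#' @export
temporal_sd_map <- function(series) {
  stopifnot(inherits(series, "r2star_series"))
  X <- series_matrix(series)
  sds <- apply(X, 2L, sd)
  out <- array(NA_real_, dim(series$mask))
  out[series$mask] <- sds
  summary_map(out, series$mask, label = "temporal_sd")
}

#' Convert frequencies between Hz and cycles per hour
#'
#' The sub-milliHertz oscillations relevant to cycling tumour oxygenation are
#' conventionally reported both in Hz and in cycles per hour
#' (1e-3 Hz = 3.6 cycles/h).
#'
#' @param f Frequency in Hz (or cycles per hour for the inverse).
#' @return Numeric of the same length.
#' @export
hz_to_cycles_per_hour <- function(f) f * 3600

#' @rdname hz_to_cycles_per_hour
#' @export
cycles_per_hour_to_hz <- function(f) f / 3600
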