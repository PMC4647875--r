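#' Average power spectrum over voxels
#'
#' Each voxel time-course is mean-removed (no window, no detrending) and
#' Fourier transformed; per-bin power |DFT|^2 / n is averaged arithmetically
#' over voxels. The one-sided spectrum excludes the zero-frequency bin and
#' runs to Nyquist = 1 / (2 frame_interval), with bin width
#' 1 / (n_frames * frame_interval).
#'
#' @param field Time x voxel matrix (e.g. a reconstructed class field), or an
#'   [r2star_series()].
#' @param frame_interval Seconds per frame (taken from the series if one is
#'   given).
#' @param voxels Optional logical or integer selection of columns.
#' @return A tibble of class `spectrum_result` with columns `frequency_hz`,
#'   `power`, and attributes `n_frames`, `frame_interval`, `n_voxels`.
#' @export
average_spectrum <- function(field, frame_interval = NULL, voxels = NULL) {
  if (inherits(field, "r2star_series")) {
    frame_interval <- field$frame_interval
    field <- series_matrix(field)
  }
  if (is.null(frame_interval)) stop("`frame_interval` is required", call. = FALSE)
  X <- as.matrix(field)
  if (!is.null(voxels)) X <- X[, voxels, drop = FALSE]
  n <- nrow(X)
  if (n < 8L) stop("need at least 8 frames", call. = FALSE)
  if (ncol(X) < 1L) stop("empty voxel set", call. = FALSE)
  Xc <- sweep(X, 2L, colMeans(X))
  P <- Mod(stats::mvfft(Xc))^2 / n
  nb <- floor(n / 2)
  power <- rowMeans(P[2:(nb + 1), , drop = FALSE])
  out <- tibble::tibble(frequency_hz = seq_len(nb) / (n * frame_interval),
                        power = power)
  attr(out, "n_frames") <- n
  attr(out, "frame_interval") <- frame_interval
  attr(out, "n_voxels") <- ncol(X)
  class(out) <- c("spectrum_result", class(out))
  out
}

#' Dominant frequency of a spectrum
#'
#' Frequency of the maximum-power bin (peak height); ties break toward the
#' lower frequency. An all-zero spectrum has no dominant frequency and
#' returns `NA` with a warning.
#'
#' @param spectrum An [average_spectrum()] result (or any tibble with
#'   `frequency_hz` and `power`).
#' @return Frequency in Hz.
#' @export
dominant_frequency <- function(spectrum) {
  if (nrow(spectrum) == 0L) stop("empty spectrum", call. = FALSE)
  if (all(spectrum$power == 0)) {
    warning("all-zero spectrum: dominant frequency undefined", call. = FALSE)
    return(NA_real_)
  }
  spectrum$frequency_hz[which.max(spectrum$power)]
}

#' Cohort mean and s.d. of spectra
#'
#' Per-bin mean and sample standard deviation over a cohort of tumours'
#' average spectra, which must share one frequency grid. With a single
#' spectrum the s.d. is zero.
#'
#' @param spectra List of [average_spectrum()] results.
#' @return Tibble: `frequency_hz`, `mean_power`, `sd_power`.
#' @export
cohort_spectra <- function(spectra) {
  if (length(spectra) < 1L) stop("need at least one spectrum", call. = FALSE)
  f0 <- spectra[[1L]]$frequency_hz
  for (s in spectra)
    if (!isTRUE(all.equal(s$frequency_hz, f0)))
      stop("spectra do not share a frequency grid", call. = FALSE)
  P <- vapply(spectra, function(s) s$power, numeric(length(f0)))
  P <- matrix(P, nrow = length(f0))
  sds <- if (ncol(P) == 1L) rep(0, length(f0)) else apply(P, 1L, sd)
  tibble::tibble(frequency_hz = f0, mean_power = rowMeans(P), sd_power = sds)
}

#' @export
autoplot.spectrum_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$frequency_hz, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)", y = "Power",
                  title = "Average power spectrum") +
    ggplot2::theme_minimal()
}
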