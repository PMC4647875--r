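#' Fluorescence coverage fraction within an ROI
#'
#' Fraction of ROI pixels whose channel intensity exceeds the background
#' threshold: the standard per-marker coverage statistic for fluorescently
#' labelled tumour sections (CD31, alpha-SMA, Hoechst 33342, pimonidazole).
#' The threshold is a required input because background levels are
#' section-specific; [otsu_threshold()] offers a conventional default.
#'
#' @param channel Numeric matrix of pixel intensities (>= 0).
#' @param roi Logical matrix marking the tumour region of interest.
#' @param threshold Background intensity threshold (>= 0).
#' @return Fraction in \[0, 1\].
#' @export
coverage_fraction <- function(channel, roi, threshold) {
  stopifnot(is.matrix(channel) || is.array(channel))
  roi <- array(as.logical(roi), dim(roi))
  if (!identical(dim(channel), dim(roi)))
    stop("`channel` and `roi` dimensions must match", call. = FALSE)
  if (!any(roi)) stop("empty ROI", call. = FALSE)
  if (!is.numeric(threshold) || threshold < 0)
    stop("`threshold` must be a number >= 0", call. = FALSE)
  mean(channel[roi] > threshold)
}

#' Pericyte coverage of vessels
#'
#' Percentage of endothelial (CD31-positive) pixels colocalised with
#' alpha-SMA staining within the ROI: a pixel-wise proxy for vascular
#' maturation. Undefined (NA, with a warning) when the ROI contains no CD31
#' pixels.
#'
#' @param cd31_mask,sma_mask Logical matrices of thresholded staining.
#' @param roi Logical ROI matrix.
#' @return Percent in \[0, 100\], or `NA`.
#' @export
pericyte_vessel_coverage <- function(cd31_mask, sma_mask, roi) {
  roi <- array(as.logical(roi), dim(roi))
  cd <- array(as.logical(cd31_mask), dim(cd31_mask)) & roi
  sm <- array(as.logical(sma_mask), dim(sma_mask)) & roi
  if (!identical(dim(cd), dim(sm)))
    stop("mask dimensions must match", call. = FALSE)
  if (!any(cd)) {
    warning("no CD31-positive pixels in ROI: coverage undefined", call. = FALSE)
    return(NA_real_)
  }
  100 * sum(cd & sm) / sum(cd)
}

#' Otsu background threshold within an ROI
#'
#' Convenience default for [coverage_fraction()]: Otsu's criterion applied to
#' the ROI pixel intensities (via EBImage), rescaled back to the channel's
#' intensity range. The chosen threshold should always be reported alongside
#' the coverage values.
#'
#' @param channel Numeric intensity matrix.
#' @param roi Logical ROI matrix (defaults to the whole image).
#' @return Threshold on the channel's intensity scale.
#' @export
otsu_threshold <- function(channel, roi = NULL) {
  if (!requireNamespace("EBImage", quietly = TRUE))
    stop("`EBImage` is required for otsu_threshold()", call. = FALSE)
  if (is.null(roi)) roi <- array(TRUE, dim(channel))
  v <- channel[array(as.logical(roi), dim(roi))]
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  img <- EBImage::Image(matrix((v - rng[1]) / diff(rng), ncol = 1L))
  th <- EBImage::otsu(img, range = c(0, 1))
  rng[1] + th * diff(rng)
}

#' Read a single-channel section image
#'
#' Reads TIFF or PNG into a numeric intensity matrix (first channel of a
#' multi-channel image, with a message).
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @return Numeric matrix.
#' @export
read_section_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("`tiff` is required to read TIFF images", call. = FALSE)
      tiff::readTIFF(path)
    },
    png = {
      if (!requireNamespace("png", quietly = TRUE))
        stop("`png` is required to read PNG images", call. = FALSE)
      png::readPNG(path)
    },
    stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(img)) == 3L) {
    message("multi-channel image: using channel 1")
    img <- img[, , 1L]
  }
  img
}

#' Coverage metrics for one section
#'
#' Applies [coverage_fraction()] to each named channel of a section and
#' returns a tidy per-channel table.
#'
#' @param channels Named list of intensity matrices.
#' @param roi Logical ROI matrix.
#' @param thresholds Named numeric vector of per-channel background
#'   thresholds, or `"otsu"` to derive each with [otsu_threshold()].
#' @return Tibble: `channel`, `threshold`, `coverage`.
#' @export
section_coverage <- function(channels, roi, thresholds = "otsu") {
  stopifnot(is.list(channels), length(channels) >= 1L, !is.null(names(channels)))
  purrr::map_dfr(names(channels), function(nm) {
    th <- if (identical(thresholds, "otsu")) otsu_threshold(channels[[nm]], roi)
          else thresholds[[nm]]
    tibble::tibble(channel = nm, threshold = th,
                   coverage = coverage_fraction(channels[[nm]], roi, th))
  })
}
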