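#' Load a dynamic R2* series from NIfTI
#'
#' Reads a 4D NIfTI volume and a 3D mask, validating that their spatial
#' shapes match and that in-mask values are finite. The frame interval is
#' taken from the NIfTI timing header (`pixdim[4]`) unless overridden by
#' `frame_interval`, which wins with a message.
#'
#' @param path Path to the 4D R2* volume (NIfTI-1).
#' @param mask_path Path to a 3D mask volume (non-zero = in mask).
#' @param frame_interval Optional override, seconds per frame.
#' @return An [r2star_series()].
#' @export
load_series <- function(path, mask_path, frame_interval = NULL) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L)
    stop("expected a 4D volume in ", path, call. = FALSE)
  msk <- RNifti::readNifti(mask_path)
  if (!identical(dim(msk)[1:3], dim(img)[1:3]))
    stop("mask and series spatial dimensions differ", call. = FALSE)
  hdr_dt <- RNifti::pixdim(img)[4]
  if (is.null(frame_interval)) {
    if (!is.finite(hdr_dt) || hdr_dt <= 0)
      stop("no usable frame timing in the NIfTI header; supply `frame_interval`",
           call. = FALSE)
    frame_interval <- hdr_dt
  } else if (is.finite(hdr_dt) && hdr_dt > 0 &&
             abs(hdr_dt - frame_interval) > 1e-6) {
    message("overriding header frame interval ", signif(hdr_dt, 4),
            " s with ", signif(frame_interval, 4), " s")
  }
  r2star_series(array(as.numeric(img), dim(img)), frame_interval,
                mask = array(as.numeric(msk) > 0, dim(msk)[1:3]))
}

#' Write a series, mask or map as NIfTI
#'
#' Series and summary maps are written as 32-bit float, masks as 8-bit
#' unsigned integers. The frame interval is stored in the timing header.
#'
#' @param x An [r2star_series()], [summary_map()], or logical/numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(x, path) {
  if (inherits(x, "r2star_series")) {
    vs <- if (is.null(x$voxel_size)) c(1, 1, 1) else x$voxel_size
    img <- RNifti::asNifti(
      x$values, datatype = "float",
      reference = list(pixdim = c(-1, vs, x$frame_interval, 0, 0, 0)))
    RNifti::writeNifti(img, path)
  } else if (inherits(x, "summary_map")) {
    v <- x$values
    v[is.na(v)] <- 0
    RNifti::writeNifti(RNifti::asNifti(v, datatype = "float"), path)
  } else if (is.logical(x)) {
    RNifti::writeNifti(RNifti::asNifti(array(as.integer(x), dim(x)),
                                       datatype = "uint8"), path)
  } else {
    RNifti::writeNifti(RNifti::asNifti(x, datatype = "float"), path)
  }
  invisible(path)
}

#' Save a synthetic dataset to disk
#'
#' Writes the phantom series and mask as NIfTI, the O2sat trace as CSV
#' (`time_s,o2sat_pct`), the ground-truth label maps as 8-bit NIfTI, and the
#' injected parameters as JSON.
#'
#' @param phantom A [generate_phantom()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_nifti_volume(phantom$series, file.path(dir, "series.nii.gz"))
  write_nifti_volume(phantom$series$mask, file.path(dir, "mask.nii.gz"))
  write_nifti_volume(phantom$truth_systemic,
                     file.path(dir, "truth_systemic.nii.gz"))
  write_nifti_volume(phantom$truth_tumour_specific,
                     file.path(dir, "truth_tumour_specific.nii.gz"))
  write_o2sat(phantom$o2sat, file.path(dir, "o2sat.csv"))
  params <- phantom$params
  params$clusters <- if (!is.null(params$clusters)) as.data.frame(params$clusters)
  jsonlite::write_json(params, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname read_o2sat
#' @export
load_o2sat <- function(path) read_o2sat(path)
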