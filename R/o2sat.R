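#' Systemic arterial oxygen-saturation trace
#'
#' Timestamped systemic arterial oxyhaemoglobin saturation (O2sat, percent)
#' from pulse oximetry, recorded concurrently with the MRI acquisition. The
#' trace is the external reference against which independent-component
#' time-courses are correlated to identify systemic oxygenation dynamics.
#'
#' @param times Seconds from acquisition start, strictly increasing.
#' @param values O2sat in percent, within \[0, 100\].
#' @return A tibble of class `o2sat_trace` with columns `time_s`, `o2sat_pct`.
#' @examples
#' o2sat_trace(0:9, 95 + sin(0:9 / 3))
#' @export
o2sat_trace <- function(times, values) {
  if (length(times) != length(values) || length(times) < 2L)
    stop("`times` and `values` must have equal length >= 2", call. = FALSE)
  if (anyNA(times) || anyNA(values) || !all(is.finite(values)))
    stop("O2sat trace must be finite and free of NA", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("`times` must be strictly increasing", call. = FALSE)
  if (any(values < 0 | values > 100))
    stop("O2sat values must lie in [0, 100] percent", call. = FALSE)
  out <- tibble::tibble(time_s = as.numeric(times), o2sat_pct = as.numeric(values))
  class(out) <- c("o2sat_trace", class(out))
  out
}

#' Read an O2sat trace from delimited text
#'
#' Expects two columns, time in seconds and O2sat in percent
#' (`time_s,o2sat_pct`); extra columns are ignored. Validation (monotone
#' times, values within \[0, 100\]) is applied on construction.
#'
#' @param path Path to a CSV file.
#' @return An [o2sat_trace()].
#' @export
read_o2sat <- function(path) {
  d <- read.csv(path)
  if (ncol(d) < 2L) stop("expected at least two columns (time_s, o2sat_pct)", call. = FALSE)
  o2sat_trace(d[[1L]], d[[2L]])
}

#' Write an O2sat trace to CSV
#'
#' @param o2sat An [o2sat_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_o2sat <- function(o2sat, path) {
  stopifnot(inherits(o2sat, "o2sat_trace"))
  utils::write.csv(as.data.frame(o2sat), path, row.names = FALSE)
  invisible(path)
}

#' Resample an O2sat trace to MRI frame midpoints
#'
#' Linear interpolation of the (typically 1 Hz) oximetry trace to the midpoint
#' of each MRI frame, the alignment used by every O2sat correlation in the
#' pipeline. No temporal lag is modelled: murine circulation time is far below
#' the frame interval.
#'
#' @param o2sat An [o2sat_trace()].
#' @param n_frames Number of MRI frames.
#' @param frame_interval Seconds per frame.
#' @return Numeric vector of length `n_frames`.
#' @export
o2sat_at_frames <- function(o2sat, n_frames, frame_interval) {
  stopifnot(inherits(o2sat, "o2sat_trace"))
  mids <- frame_midpoints(n_frames, frame_interval)
  if (min(o2sat$time_s) > mids[1] + frame_interval ||
      max(o2sat$time_s) < mids[n_frames] - frame_interval)
    warning("O2sat trace does not cover the acquisition window; ",
            "edge values are extrapolated as constants", call. = FALSE)
  approx(o2sat$time_s, o2sat$o2sat_pct, xout = mids, rule = 2)$y
}
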