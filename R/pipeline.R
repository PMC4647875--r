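#' Analysis parameters for the full pipeline
#'
#' Collects every tunable threshold with the defaults used throughout:
#' component-level O2sat significance 0.01, voxel-level thresholds 0.01
#' (systemic) and 0.05 (tumour-specific non-significance), |z| >= 2.2 map
#' threshold, minimum cluster of 5 voxels, face (6-neighbour) connectivity,
#' dominant-peak ratio 30, distinctiveness (lag-1 autocorrelation) 0.3, and
#' the FastICA settings. Every value is echoed verbatim into the run report.
#'
#' @param p_systemic,p_tumour_specific,z_threshold Correlation and map
#'   thresholds.
#' @param min_cluster,connectivity,peak_ratio,distinctiveness_threshold
#'   Cluster and time-course criteria.
#' @param ica_seed,ica_tol,ica_maxit FastICA settings.
#' @return A named list of class `pipeline_params`.
#' @export
pipeline_params <- function(p_systemic = 0.01,
                            p_tumour_specific = 0.05,
                            z_threshold = 2.2,
                            min_cluster = 5L,
                            connectivity = 6L,
                            peak_ratio = 30,
                            distinctiveness_threshold = 0.3,
                            ica_seed = 0L,
                            ica_tol = 1e-4,
                            ica_maxit = 1000L) {
  p <- list(p_systemic = p_systemic, p_tumour_specific = p_tumour_specific,
            z_threshold = z_threshold, min_cluster = as.integer(min_cluster),
            connectivity = as.integer(connectivity), peak_ratio = peak_ratio,
            distinctiveness_threshold = distinctiveness_threshold,
            ica_seed = as.integer(ica_seed), ica_tol = ica_tol,
            ica_maxit = as.integer(ica_maxit))
  if (any(vapply(p[1:7], function(v) !is.numeric(v) || v <= 0, logical(1))))
    stop("all thresholds must be positive", call. = FALSE)
  structure(p, class = "pipeline_params")
}

#' Run the full decomposition pipeline
#'
#' End-to-end analysis of one tumour: PCA with shoulder-plus-peak eigenvector
#' selection, spatial ICA, component classification against the O2sat trace,
#' class-wise reconstruction, voxel thresholding, and frequency-domain
#' summaries of the thresholded class fields. Deterministic under the ICA
#' seed in `params`. Stage progress and eigenvector counts are logged with
#' `message()`.
#'
#' @param series An [r2star_series()].
#' @param o2sat An [o2sat_trace()].
#' @param params A [pipeline_params()] list.
#' @return An object of class `fluctuation_report`: `selection` diagnostics,
#'   component `labels`, `fields` ([threshold_voxels()] result), per-class
#'   average `spectra` and `dominant_frequencies` of the thresholded voxels,
#'   the `params` used, and a `summary` tibble.
#' @export
run_pipeline <- function(series, o2sat, params = pipeline_params()) {
  stopifnot(inherits(series, "r2star_series"), inherits(o2sat, "o2sat_trace"),
            inherits(params, "pipeline_params"))
  message("PCA decomposition ...")
  pca <- pca_decompose(series)
  sel <- select_eigenvectors(pca, peak_ratio = params$peak_ratio)
  message(sprintf("selected %d of %d eigenvectors (shoulder at %d, %d peak-rule)",
                  length(sel$selected), length(pca$eigenvalues),
                  sel$shoulder_index, length(sel$peak_set)))
  xr <- reduce_series(pca, sel)
  message("spatial ICA (k = ", length(sel$selected), ") ...")
  ica <- run_spatial_ica(xr, seed = params$ica_seed, tol = params$ica_tol,
                         maxit = params$ica_maxit)
  message("classifying components ...")
  labels <- classify_components(
    ica, o2sat,
    p_systemic = params$p_systemic, peak_ratio = params$peak_ratio,
    z_threshold = params$z_threshold, min_cluster = params$min_cluster,
    connectivity = params$connectivity,
    distinctiveness_threshold = params$distinctiveness_threshold)
  counts <- table(factor(labels$class,
                         levels = c("systemic", "tumour_specific", "noise")))
  message(sprintf("components: %d systemic, %d tumour-specific, %d noise",
                  counts[1], counts[2], counts[3]))
  fields <- threshold_voxels(
    ica, labels, o2sat, series,
    p_systemic = params$p_systemic,
    p_tumour_specific = params$p_tumour_specific,
    z_threshold = params$z_threshold)

  spec_of <- function(X, maskvol) {
    keep <- maskvol[series$mask]
    if (!any(keep)) return(NULL)
    average_spectrum(X, series$frame_interval, voxels = keep)
  }
  spectra <- list(
    systemic = spec_of(fields$X_systemic, fields$systemic_mask),
    tumour_specific = spec_of(fields$X_tumour_specific,
                              fields$tumour_specific_mask))
  domfreq <- purrr::map_dbl(spectra, function(s)
    if (is.null(s)) NA_real_ else dominant_frequency(s))

  summary <- dplyr::mutate(fields$summary,
                           dominant_frequency_hz = unname(domfreq),
                           dominant_cycles_per_hour =
                             hz_to_cycles_per_hour(unname(domfreq)))
  structure(
    list(selection = sel,
         labels = labels,
         fields = fields,
         spectra = spectra,
         summary = summary,
         n_eigenvalues = length(pca$eigenvalues),
         params = params,
         n_frames = dim(series$values)[4],
         frame_interval = series$frame_interval),
    class = "fluctuation_report"
  )
}

#' @export
print.fluctuation_report <- function(x, ...) {
  cat("<fluctuation_report>\n")
  cat(sprintf("  %d/%d eigenvectors selected; %d ICA components\n",
              length(x$selection$selected), x$n_eigenvalues, nrow(x$labels)))
  print(x$summary)
  invisible(x)
}

#' @describeIn run_pipeline Class-level summary tibble (prevalence %, mean
#'   temporal s.d., dominant frequency).
#' @export
glance.fluctuation_report <- function(x, ...) x$summary

#' @describeIn run_pipeline Component label table.
#' @export
tidy.fluctuation_report <- function(x, ...) x$labels

#' Write a run report to disk
#'
#' Serialises the audit trail of a pipeline run: every threshold and seed,
#' eigenvector counts, the component label table, the class summary, and the
#' intermediate-band voxel count, as JSON; optionally the class masks and
#' per-class temporal s.d. maps as NIfTI.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if missing).
#' @param volumes Write NIfTI masks and s.d. maps as well?
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, volumes = TRUE) {
  stopifnot(inherits(report, "fluctuation_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  payload <- list(
    params = unclass(report$params),
    n_frames = report$n_frames,
    frame_interval = report$frame_interval,
    n_eigenvalues = report$n_eigenvalues,
    n_selected = length(report$selection$selected),
    shoulder_index = report$selection$shoulder_index,
    n_peak_selected = length(report$selection$peak_set),
    components = as.data.frame(report$labels),
    class_summary = as.data.frame(report$summary),
    n_intermediate_voxels = report$fields$n_intermediate
  )
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  utils::write.csv(as.data.frame(report$labels),
                   file.path(dir, "components.csv"), row.names = FALSE)
  if (volumes) {
    f <- report$fields
    write_nifti_volume(f$systemic_mask, file.path(dir, "systemic_mask.nii.gz"))
    write_nifti_volume(f$tumour_specific_mask,
                       file.path(dir, "tumour_specific_mask.nii.gz"))
    msk <- report$fields$mask
    for (cls in c("X_systemic", "X_tumour_specific")) {
      sds <- apply(f[[cls]], 2L, sd)
      vol <- array(0, dim(msk)); vol[msk] <- sds
      write_nifti_volume(vol, file.path(dir, paste0(sub("X_", "sd_", cls), ".nii.gz")))
    }
  }
  invisible(dir)
}
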