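#' Correlate a time-course with the O2sat trace
#'
#' Pearson correlation between a component (or voxel) time-course and the
#' systemic O2sat trace linearly interpolated to the MRI frame midpoints,
#' with the two-sided p-value from t = r sqrt((n - 2) / (1 - r^2)) on n - 2
#' degrees of freedom. No temporal lag is modelled.
#'
#' @param timecourse Numeric vector, length >= 4.
#' @param o2sat An [o2sat_trace()].
#' @param frame_interval Seconds per frame.
#' @return One-row tibble: `r`, `p`, `n`, `flagged` (TRUE when the
#'   correlation is undefined because an input has zero variance; `p` is then
#'   reported as 1).
#' @export
pearson_vs_o2sat <- function(timecourse, o2sat, frame_interval) {
  n <- length(timecourse)
  if (n < 4L) stop("need at least 4 frames", call. = FALSE)
  y <- o2sat_at_frames(o2sat, n, frame_interval)
  if (sd(timecourse) == 0 || sd(y) == 0)
    return(tibble::tibble(r = NA_real_, p = 1, n = n, flagged = TRUE))
  res <- pearson_t_p(timecourse, y)
  tibble::tibble(r = res$estimate, p = res$p.value, n = n, flagged = FALSE)
}

#' Threshold a spatial map by z-score
#'
#' Normalises a component spatial map to zero mean and unit variance over the
#' in-mask voxels and keeps voxels with |z| at or above the threshold. The
#' default threshold 2.2 keeps ~2.8% of voxels of a pure-noise map.
#'
#' @param map Numeric vector, one value per in-mask voxel (a row of S).
#' @param z_threshold |z| cut-off.
#' @return Logical vector with attributes `z` (the z-scored map) and
#'   `flagged` (TRUE for a constant map, which yields an empty result).
#' @export
zscore_threshold_map <- function(map, z_threshold = 2.2) {
  if (length(map) < 2L) stop("map must have more than one voxel", call. = FALSE)
  s <- sd(map)
  if (s == 0)
    return(structure(rep(FALSE, length(map)),
                     z = rep(NA_real_, length(map)), flagged = TRUE))
  z <- (map - mean(map)) / s
  structure(abs(z) >= z_threshold, z = z, flagged = FALSE)
}

#' Find connected voxel clusters
#'
#' Connected components of a thresholded boolean map under face (6-neighbour)
#' 3D connectivity, discarding components below the minimum size. Components
#' are found on the voxel adjacency graph with `igraph`.
#'
#' @param keep Logical: either a 3D array, or a vector over in-mask voxels
#'   (in which case `mask` must be given to place voxels in 3D).
#' @param mask Logical 3D array locating the in-mask voxels of `keep`.
#' @param min_size Minimum cluster size in voxels.
#' @param connectivity 6 (faces), 18 (+edges) or 26 (+corners).
#' @return Tibble with one row per cluster: `cluster`, `size`, and `voxels`
#'   (list-column of linear voxel indices into the 3D grid), ordered by
#'   decreasing size.
#' @export
find_clusters <- function(keep, mask = NULL, min_size = 5L, connectivity = 6L) {
  if (!is.array(keep) || length(dim(keep)) != 3L) {
    if (is.null(mask))
      stop("`mask` is required when `keep` is a vector over mask voxels", call. = FALSE)
    vol <- array(FALSE, dim(mask))
    vol[mask] <- as.logical(keep)
  } else vol <- array(as.logical(keep), dim(keep))
  vol[is.na(vol)] <- FALSE
  idx <- which(vol)
  empty <- tibble::tibble(cluster = integer(0), size = integer(0),
                          voxels = list())
  if (length(idx) == 0L) return(empty)
  d <- dim(vol)
  co <- arrayInd(idx, d)
  id <- seq_along(idx)
  pos <- array(0L, d); pos[idx] <- id
  offs <- switch(as.character(connectivity),
    "6" = rbind(c(1,0,0), c(0,1,0), c(0,0,1)),
    "18" = , "26" = {
      g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
      g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
      if (connectivity == 18L) g <- g[rowSums(abs(g)) <= 2, , drop = FALSE]
      g[seq_len(nrow(g) / 2), , drop = FALSE]  # one of each +/- pair
    },
    stop("`connectivity` must be 6, 18 or 26", call. = FALSE))
  edges <- NULL
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(co, 2L, offs[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nbid <- pos[nb[ok, , drop = FALSE]]
    hit <- nbid > 0L
    if (any(hit))
      edges <- rbind(edges, cbind(id[ok][hit], nbid[hit]))
  }
  g <- igraph::make_empty_graph(n = length(id), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  keep_comp <- which(comp$csize >= min_size)
  if (length(keep_comp) == 0L) return(empty)
  out <- tibble::tibble(
    cluster = seq_along(keep_comp),
    size = as.integer(comp$csize[keep_comp]),
    voxels = lapply(keep_comp, function(cc) sort(idx[comp$membership == cc]))
  )
  dplyr::arrange(out, dplyr::desc(.data$size))
}

#' Temporal distinctiveness of a time-course
#'
#' Lag-1 autocorrelation, used to separate "distinctive" (slowly varying,
#' structured) component time-courses from noise-like ones: a slow oscillation
#' sampled at interval dt has lag-1 autocorrelation cos(2 pi f dt) ~ 1,
#' whereas white noise scatters around 0 with s.e. ~ 1/sqrt(n).
#'
#' @param timecourse Numeric vector, length >= 8.
#' @return Lag-1 autocorrelation; `NA` (flagged fail) for a constant input.
#' @export
distinctiveness <- function(timecourse) {
  if (length(timecourse) < 8L) stop("time-course must have length >= 8", call. = FALSE)
  if (sd(timecourse) == 0) return(NA_real_)
  as.vector(acf(timecourse, lag.max = 1L, plot = FALSE,
                demean = TRUE)$acf[2L])
}

#' Classify independent components
#'
#' Assigns each component to one of three classes. A component whose
#' time-course carries O2sat-related signal at p < `p_systemic` is
#' `systemic`. Otherwise it is `tumour_specific` if its time-course has a
#' dominant frequency peak, or if its z-thresholded spatial map contains at
#' least one cluster of `min_cluster` voxels *and* its time-course is
#' distinctive (lag-1 autocorrelation at or above
#' `distinctiveness_threshold`). Anything else is `noise`. All tests are
#' two-sided / magnitude-based, so the ICA sign indeterminacy cannot change a
#' label. No multiple-testing correction is applied (raw p thresholds).
#'
#' The systemic test is the marginal Pearson correlation of each component
#' time-course with the interpolated O2sat trace ([pearson_vs_o2sat()]).
#' Note that at ~1000 frames p < 0.01 corresponds to |r| > 0.084, so the
#' rule is sensitive to small temporal admixtures between components; the
#' decomposition upstream must therefore be well conditioned (see the
#' package vignette on identifiability).
#'
#' @param ica A [run_spatial_ica()] result (with geometry carried).
#' @param o2sat An [o2sat_trace()].
#' @param p_systemic Component-level O2sat significance threshold.
#' @param peak_ratio Dominant-peak threshold, see [has_dominant_peak()].
#' @param z_threshold,min_cluster,connectivity Spatial-cluster criterion, see
#'   [zscore_threshold_map()] and [find_clusters()].
#' @param distinctiveness_threshold Minimum lag-1 autocorrelation for the
#'   cluster route.
#' @return Tibble with one row per component: `component`, `class`,
#'   `o2sat_r`, `o2sat_p`, `peak`, `peak_freq_hz`, `peak_ratio_observed`,
#'   `n_clusters`, `max_cluster_size`, `distinctiveness`.
#' @export
classify_components <- function(ica, o2sat,
                                p_systemic = 0.01,
                                peak_ratio = 30,
                                z_threshold = 2.2,
                                min_cluster = 5L,
                                connectivity = 6L,
                                distinctiveness_threshold = 0.3) {
  stopifnot(inherits(ica, "spatial_ica"))
  if (is.null(ica$mask))
    stop("ICA object carries no mask; rerun from `reduce_series()`", call. = FALSE)
  purrr::map_dfr(seq_len(ica$k), function(j) {
    tc <- ica$M[, j]
    co <- pearson_vs_o2sat(tc, o2sat, ica$frame_interval)
    pk <- has_dominant_peak(tc, ica$frame_interval, peak_ratio = peak_ratio)
    thr <- zscore_threshold_map(ica$S[j, ], z_threshold = z_threshold)
    cl <- find_clusters(thr, mask = ica$mask, min_size = min_cluster,
                        connectivity = connectivity)
    ds <- distinctiveness(tc)
    cls <- if (!co$flagged && co$p < p_systemic) "systemic"
      else if (pk$peak) "tumour_specific"
      else if (nrow(cl) >= 1L && !is.na(ds) && ds >= distinctiveness_threshold)
        "tumour_specific"
      else "noise"
    tibble::tibble(
      component = j, class = cls,
      o2sat_r = co$r, o2sat_p = co$p,
      peak = pk$peak, peak_freq_hz = pk$frequency,
      peak_ratio_observed = pk$ratio,
      n_clusters = nrow(cl),
      max_cluster_size = if (nrow(cl)) max(cl$size) else 0L,
      distinctiveness = ds
    )
  })
}

#' Reconstruct the R2* field of one component class
#'
#' The reverse of the ICA decomposition restricted to one class: the product
#' of the mixing-matrix columns and spatial-map rows of the components
#' carrying that label. Class fields are additive: summing over all classes
#' recovers M %*% S exactly.
#'
#' @param ica A [run_spatial_ica()] result.
#' @param labels A [classify_components()] tibble.
#' @param class One of `"systemic"`, `"tumour_specific"`, `"noise"`.
#' @return Time x voxel matrix (all zeros when the class is empty).
#' @export
reconstruct_class <- function(ica, labels, class) {
  stopifnot(inherits(ica, "spatial_ica"))
  class <- match.arg(class, c("systemic", "tumour_specific", "noise"))
  idx <- labels$component[labels$class == class]
  if (length(idx) == 0L) return(matrix(0, nrow(ica$M), ncol(ica$S)))
  ica$M[, idx, drop = FALSE] %*% ica$S[idx, , drop = FALSE]
}

#' Threshold voxels into systemic and tumour-specific maps
#'
#' Voxel-level attribution of the two signal classes, applying the
#' correlation thresholds p < `p_systemic` (systemic) and
#' p > `p_tumour_specific` (tumour-specific non-significance) to per-voxel
#' Pearson tests against the O2sat trace.
#'
#' Two refinements keep the voxel tests calibrated. First, each class is
#' tested on the *data* with the other class's reconstruction removed
#' (systemic test on X - X_hat_tsp, tumour-specific test on X - X_hat_sys)
#' rather than on the class reconstruction alone: Pearson correlation is
#' scale-invariant, so a class field built from few components is (near)
#' rank-deficient and every voxel with nonzero map weight would share one
#' |r|, while the data-based test retains each voxel's own noise and has the
#' nominal false-positive rate at null voxels. Removing the other class
#' still lets a voxel carrying both signals enter both masks. Second, the
#' tumour-specific rule is a *non*-significance test, which any pure-noise
#' voxel passes; it is therefore gated to voxels with |z| >= `z_threshold`
#' in at least one tumour-specific component map (the same z-thresholding
#' applied to those maps during classification). A class with no components
#' yields an empty mask. Voxels whose tumour-specific test falls in the
#' intermediate band \[`p_systemic`, `p_tumour_specific`\] are excluded from
#' both masks and counted.
#'
#' A voxel whose tested field retains less than `min_residual_frac` of its
#' raw temporal s.d. is flagged as fully explained by the removed class and
#' excluded: after near-exact cancellation the residual consists of the
#' reconstruction's own estimation dust, whose correlation with O2sat is
#' arbitrary. The floor only matters for (near-)noiseless data — measurement
#' noise keeps real residuals far above 5% of the raw fluctuation.
#'
#' @inheritParams classify_components
#' @param labels A [classify_components()] tibble.
#' @param series The [r2star_series()] the decomposition was run on.
#' @param p_tumour_specific Non-significance threshold for the
#'   tumour-specific voxel rule.
#' @param min_residual_frac Fraction of the raw voxel s.d. below which a
#'   tested residual field is considered information-free.
#' @return An object of class `fluctuation_fields`: logical 3D masks
#'   `systemic_mask` and `tumour_specific_mask`, the class fields
#'   `X_systemic`, `X_tumour_specific`, `X_noise` (time x voxel), a per-voxel
#'   tibble `voxel_stats` (`voxel` = linear 3D index, per-class `r`, `p`),
#'   and a one-row `summary` tibble with prevalence (% of mask voxels) and
#'   mean temporal s.d. of each class field within its mask.
#' @export
threshold_voxels <- function(ica, labels, o2sat, series,
                             p_systemic = 0.01,
                             p_tumour_specific = 0.05,
                             z_threshold = 2.2,
                             min_residual_frac = 0.05) {
  stopifnot(inherits(ica, "spatial_ica"), inherits(series, "r2star_series"))
  Tn <- nrow(ica$M); V <- ncol(ica$S)
  mask <- ica$mask
  X <- series_matrix(series)
  if (nrow(X) != Tn || ncol(X) != V)
    stop("`series` does not match the decomposition dimensions", call. = FALSE)
  Xc <- sweep(X, 2L, colMeans(X))
  y <- o2sat_at_frames(o2sat, Tn, ica$frame_interval)
  Xsys <- reconstruct_class(ica, labels, "systemic")
  Xtsp <- reconstruct_class(ica, labels, "tumour_specific")
  Xnoise <- reconstruct_class(ica, labels, "noise")
  have_sys <- any(labels$class == "systemic")
  have_tsp <- any(labels$class == "tumour_specific")

  ref_sd <- apply(Xc, 2L, sd)
  corr_p <- function(Xf) {
    sds <- apply(Xf, 2L, sd)
    r <- rep(NA_real_, V); p <- rep(1, V)
    ok <- sds > pmax(ref_sd, .Machine$double.eps) * min_residual_frac &
      sd(y) > 0
    if (any(ok)) {
      r[ok] <- as.vector(cor(y, Xf[, ok, drop = FALSE]))
      tt <- r[ok] * sqrt((Tn - 2) / pmax(1 - r[ok]^2, .Machine$double.eps))
      p[ok] <- 2 * pt(-abs(tt), df = Tn - 2)
    }
    list(r = r, p = p, ok = ok)
  }

  sys_test <- corr_p(Xc - Xtsp)
  tsp_test <- corr_p(Xc - Xsys)

  sys_keep <- if (have_sys) sys_test$ok & sys_test$p < p_systemic
              else rep(FALSE, V)
  eligible <- rep(FALSE, V)
  if (have_tsp) {
    for (j in labels$component[labels$class == "tumour_specific"])
      eligible <- eligible | zscore_threshold_map(ica$S[j, ], z_threshold)
  }
  tsp_keep <- eligible & tsp_test$ok & tsp_test$p > p_tumour_specific
  n_intermediate <- sum(eligible & tsp_test$p >= p_systemic &
                          tsp_test$p <= p_tumour_specific)

  to_vol <- function(v) { a <- array(FALSE, dim(mask)); a[mask] <- v; a }
  mean_sd <- function(X, keepv)
    if (any(keepv)) mean(apply(X[, keepv, drop = FALSE], 2L, sd)) else NA_real_

  summary <- tibble::tibble(
    class = c("systemic", "tumour_specific"),
    n_components = c(sum(labels$class == "systemic"),
                     sum(labels$class == "tumour_specific")),
    n_voxels = c(sum(sys_keep), sum(tsp_keep)),
    prevalence_pct = 100 * c(mean(sys_keep), mean(tsp_keep)),
    mean_temporal_sd = c(mean_sd(Xsys, sys_keep), mean_sd(Xtsp, tsp_keep))
  )

  structure(
    list(systemic_mask = to_vol(sys_keep),
         tumour_specific_mask = to_vol(tsp_keep),
         X_systemic = Xsys, X_tumour_specific = Xtsp, X_noise = Xnoise,
         voxel_stats = tibble::tibble(
           voxel = which(mask),
           systemic_r = sys_test$r, systemic_p = sys_test$p,
           tumour_specific_r = tsp_test$r, tumour_specific_p = tsp_test$p,
           tsp_eligible = eligible),
         summary = summary,
         n_intermediate = n_intermediate,
         thresholds = list(p_systemic = p_systemic,
                           p_tumour_specific = p_tumour_specific,
                           z_threshold = z_threshold,
                           min_residual_frac = min_residual_frac),
         mask = mask,
         frame_interval = ica$frame_interval),
    class = "fluctuation_fields"
  )
}

#' @export
print.fluctuation_fields <- function(x, ...) {
  cat("<fluctuation_fields>\n")
  print(x$summary)
  cat(sprintf("  %d voxels in the intermediate p band excluded from both masks\n",
              x$n_intermediate))
  invisible(x)
}

#' @describeIn threshold_voxels Per-voxel statistics tibble.
#' @export
tidy.fluctuation_fields <- function(x, ...) x$voxel_stats

#' @describeIn threshold_voxels Class-level summary tibble.
#' @export
glance.fluctuation_fields <- function(x, ...) x$summary
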