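#' PCA of the in-mask R2* time-courses
#'
#' Singular value decomposition of the temporally mean-centred time-by-voxel
#' matrix. Eigenvalues are reported in variance units (d^2 / (n - 1)) so that
#' their sum equals the total per-voxel temporal (sample) variance; temporal
#' eigenvectors are unit-norm time-courses; spatial scores satisfy
#' X_centred = U %*% scores. The number of eigenvalues is
#' min(n_frames, n_voxels).
#'
#' @param series An [r2star_series()].
#' @return An object of class `r2star_pca`: `eigenvalues` (descending),
#'   `eigenvectors` (frames x m, columns unit norm), `scores` (m x voxels),
#'   `total_variance`, `degenerate` flag, plus geometry (`mask`,
#'   `frame_interval`) carried for downstream stages.
#' @export
pca_decompose <- function(series) {
  stopifnot(inherits(series, "r2star_series"))
  X <- series_matrix(series)
  Tn <- nrow(X); V <- ncol(X)
  if (Tn < 2L || V < 2L)
    stop("need >= 2 frames and >= 2 mask voxels", call. = FALSE)
  Xc <- sweep(X, 2L, colMeans(X))
  sv <- svd(Xc)
  ev <- sv$d^2 / (Tn - 1)
  degenerate <- sum(ev) <= 0
  if (degenerate)
    warning("degenerate input: all time-courses constant", call. = FALSE)
  structure(
    list(eigenvalues = ev,
         eigenvectors = sv$u,
         scores = t(sv$v) * sv$d,
         total_variance = sum(ev),
         degenerate = degenerate,
         voxel_means = colMeans(X),
         mask = series$mask,
         frame_interval = series$frame_interval),
    class = "r2star_pca"
  )
}

#' @export
print.r2star_pca <- function(x, ...) {
  cat(sprintf("<r2star_pca> %d eigenvalues, total variance %.4g\n",
              length(x$eigenvalues), x$total_variance))
  cat(sprintf("  leading variance fractions: %s\n",
              paste(signif(utils::head(x$eigenvalues, 5) / x$total_variance, 3),
                    collapse = ", ")))
  invisible(x)
}

#' @export
tidy.r2star_pca <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    variance_fraction = if (x$total_variance > 0)
      x$eigenvalues / x$total_variance else rep(NA_real_, length(x$eigenvalues))
  )
}

#' Locate the shoulder of the eigenvalue curve
#'
#' The scree curve of ranked eigenvalues bends at a "shoulder" separating
#' high-variance structure from the noise floor. The shoulder is found as the
#' point of maximum perpendicular distance from the chord joining the first
#' and last points of the curve of (rank, log10 variance fraction), with both
#' axes normalised to \[0, 1\]. Ties break toward the smaller index. If the
#' curve is log-linear (chord coincides with curve) or all eigenvalues are
#' equal, index 1 is returned with attribute `flagged = TRUE`.
#'
#' @param eigenvalues Non-negative eigenvalues in descending order, length >= 3.
#' @return Integer index (1-based) with attributes `distances` (per-index
#'   perpendicular distances) and `flagged`.
#' @examples
#' find_shoulder(c(100, 1, 1, 1, 1))  # 2: the curve bends right after rank 1
#' @export
find_shoulder <- function(eigenvalues, tol = 1e-6) {
  n <- length(eigenvalues)
  if (n < 3L) stop("need at least 3 eigenvalues", call. = FALSE)
  if (is.unsorted(rev(eigenvalues))) {
    if (any(diff(eigenvalues) > max(eigenvalues) * 1e-12))
      stop("`eigenvalues` must be in descending order", call. = FALSE)
  }
  tot <- sum(eigenvalues)
  if (tot <= 0)
    return(structure(1L, distances = rep(0, n), flagged = TRUE))
  # numerically null directions (e.g. the rank lost to mean removal) carry no
  # time-course; drop them from the curve so the log axis does not plunge to
  # the floating-point floor at the tail
  m <- max(which(eigenvalues > max(eigenvalues) * 1e-12))
  if (m < 3L)  # effectively rank-deficient: every informative direction is kept
    return(structure(as.integer(m), distances = rep(0, n), flagged = FALSE))
  f <- eigenvalues[seq_len(m)] / tot
  n <- m
  y <- log10(pmax(f, max(f) * 1e-15))
  x <- seq(0, 1, length.out = n)
  if (diff(range(y)) == 0)
    return(structure(1L, distances = rep(0, n), flagged = TRUE))
  y <- (y - min(y)) / (max(y) - min(y))
  # perpendicular distance from (x_i, y_i) to the first--last chord
  dx <- x[n] - x[1]; dy <- y[n] - y[1]
  dist <- abs(dy * x - dx * y + dx * y[1] - dy * x[1]) / sqrt(dx^2 + dy^2)
  idx <- which.max(dist)  # first maximum: ties toward the smaller index
  structure(as.integer(idx), distances = dist, flagged = max(dist) < tol)
}

#' Test a time-course for a dominant frequency peak
#'
#' A time-course is deemed periodically dominated when the maximum one-sided
#' periodogram power (zero-frequency bin excluded) is at least `peak_ratio`
#' times the median power of the remaining bins. The default ratio of 30 holds
#' the white-noise false-positive rate below 1e-4 at the ~60-min acquisition
#' length (about 470 frequency bins), while injected oscillators exceed it by
#' orders of magnitude.
#'
#' @param timecourse Numeric vector, length >= 8.
#' @param frame_interval Seconds per frame.
#' @param peak_ratio Peak-to-median power threshold.
#' @return A list: `peak` (logical), `frequency` (Hz, location of the maximum
#'   bin), `ratio` (observed peak-to-median ratio, Inf if the median is 0).
#' @export
has_dominant_peak <- function(timecourse, frame_interval, peak_ratio = 30) {
  n <- length(timecourse)
  if (n < 8L) stop("time-course must have length >= 8", call. = FALSE)
  x <- timecourse - mean(timecourse)
  P <- Mod(fft(x))^2 / n
  nb <- floor(n / 2)
  P <- P[2:(nb + 1)]
  freqs <- seq_len(nb) / (n * frame_interval)
  if (all(P == 0))
    return(list(peak = FALSE, frequency = NA_real_, ratio = NA_real_))
  i <- which.max(P)
  med <- median(P[-i])
  ratio <- if (med > 0) P[i] / med else Inf
  list(peak = ratio >= peak_ratio, frequency = freqs[i], ratio = ratio)
}

#' Select eigenvectors for dimensionality reduction
#'
#' Retains all eigenvectors up to the shoulder of the eigenvalue curve, plus
#' any later eigenvector whose temporal time-course exhibits a dominant
#' frequency peak (oscillatory structure buried below the shoulder).
#'
#' @param pca An [pca_decompose()] result.
#' @param peak_ratio Passed to [has_dominant_peak()].
#' @return A list of class `eigen_selection`: `shoulder_index`,
#'   `shoulder_set`, `peak_set`, `selected` (their union, sorted), `flagged`.
#' @export
select_eigenvectors <- function(pca, peak_ratio = 30) {
  stopifnot(inherits(pca, "r2star_pca"))
  sh <- find_shoulder(pca$eigenvalues)
  shoulder_set <- seq_len(sh)
  m <- length(pca$eigenvalues)
  peak_set <- integer(0)
  if (sh < m) {
    tail_idx <- (sh + 1L):m
    # skip numerically null directions (zero variance carries no time-course)
    tail_idx <- tail_idx[pca$eigenvalues[tail_idx] >
                           max(pca$eigenvalues) * 1e-12]
    keep <- vapply(tail_idx, function(i) {
      has_dominant_peak(pca$eigenvectors[, i], pca$frame_interval,
                        peak_ratio = peak_ratio)$peak
    }, logical(1))
    peak_set <- tail_idx[keep]
  }
  structure(
    list(shoulder_index = as.integer(sh),
         shoulder_set = shoulder_set,
         peak_set = peak_set,
         selected = sort(union(shoulder_set, peak_set)),
         flagged = isTRUE(attr(sh, "flagged")),
         peak_ratio = peak_ratio),
    class = "eigen_selection"
  )
}

#' @export
print.eigen_selection <- function(x, ...) {
  cat(sprintf("<eigen_selection> shoulder at %d; %d shoulder + %d peak = %d selected\n",
              x$shoulder_index, length(x$shoulder_set), length(x$peak_set),
              length(x$selected)))
  invisible(x)
}

#' Rank-reduced data matrix
#'
#' Projects the mean-centred time-by-voxel matrix onto the selected temporal
#' eigenvectors and back: the rank-|selection| approximation of the data that
#' spatial ICA decomposes. Selecting every eigenvector reproduces the
#' mean-centred data exactly.
#'
#' @param pca An [pca_decompose()] result.
#' @param selection An [select_eigenvectors()] result, or an integer vector of
#'   eigenvector indices.
#' @return Time x voxel matrix of class `r2star_reduced`, carrying geometry
#'   attributes (`mask`, `frame_interval`, `selection`).
#' @export
reduce_series <- function(pca, selection) {
  stopifnot(inherits(pca, "r2star_pca"))
  sel <- if (inherits(selection, "eigen_selection")) selection$selected
         else as.integer(selection)
  if (length(sel) < 1L || any(sel < 1L | sel > length(pca$eigenvalues)))
    stop("invalid eigenvector selection", call. = FALSE)
  Xr <- pca$eigenvectors[, sel, drop = FALSE] %*%
    pca$scores[sel, , drop = FALSE]
  structure(Xr, class = c("r2star_reduced", "matrix", "array"),
            mask = pca$mask, frame_interval = pca$frame_interval,
            selection = sel)
}

#' Spatial independent component analysis
#'
#' Decomposes the rank-reduced time-by-voxel matrix as X = M S, where the
#' columns of the mixing matrix M are component time-courses and the rows of
#' S are spatially independent maps (FastICA, symmetric estimation, logcosh
#' contrast). The spatial mean time-course removed by ICA's internal centring
#' is refolded into S through least squares on M's columns, so M %*% S
#' reproduces the reduced matrix to numerical precision. Components are
#' canonicalised by descending explained variance, with each map's
#' largest-magnitude value made positive; results are deterministic under
#' `seed`.
#'
#' @param x_reduced A [reduce_series()] matrix (or any time x voxel matrix;
#'   supply `mask`/`frame_interval` attributes for downstream classification).
#' @param k Number of components; defaults to the selection size carried by
#'   `x_reduced`. Must not exceed the matrix rank.
#' @param seed Integer seed for the random orthogonal initialisation.
#' @param tol FastICA convergence tolerance.
#' @param maxit Iteration budget per restart.
#' @param n_restarts Number of deterministic re-initialisations (seeds
#'   `seed`, `seed + 1`, ...) attempted before non-convergence becomes an
#'   error: when the retained subspace contains near-Gaussian directions the
#'   symmetric fixed point can wander for some initialisations and settle for
#'   others.
#' @return An object of class `spatial_ica`: `M` (frames x k), `S`
#'   (k x voxels), `k`, `iterations`, `seed`, `vafs` (variance accounted
#'   for), and carried geometry.
#' @export
run_spatial_ica <- function(x_reduced, k = NULL, seed = 0L,
                            tol = 1e-4, maxit = 1000L, n_restarts = 3L) {
  Xr <- unclass(x_reduced)
  Tn <- nrow(Xr); V <- ncol(Xr)
  sel <- attr(x_reduced, "selection")
  if (is.null(k)) {
    if (is.null(sel)) stop("supply `k` (no selection attribute found)", call. = FALSE)
    k <- length(sel)
  }
  mu <- rowMeans(Xr)
  rank_c <- qr(Xr - mu)$rank
  if (k > rank_c) {
    message("requested k = ", k, " exceeds the rank ", rank_c,
            " of the voxel-centred matrix; using k = ", rank_c)
    k <- rank_c
  }
  if (k < 1L) stop("no non-degenerate components to estimate", call. = FALSE)
  fit <- NULL
  seed_used <- seed
  for (attempt in seq_len(max(1L, n_restarts))) {
    seed_used <- seed + attempt - 1L
    set.seed(seed_used)
    Rmat <- if (k == 1L) matrix(1, 1, 1) else qr.Q(qr(matrix(rnorm(k * k), k, k)))
    fit <- ica::icafast(t(Xr), nc = k, center = TRUE, maxit = maxit,
                        tol = tol, Rmat = Rmat, alg = "par", fun = "logcosh")
    if (isTRUE(fit$converged)) break
    if (attempt < n_restarts)
      message("FastICA did not converge (attempt ", attempt, "); restarting")
  }
  if (!isTRUE(fit$converged))
    stop(sprintf(paste0("FastICA did not converge within %d iterations ",
                        "(tol = %g, k = %d, %d restarts); ",
                        "increase `maxit` or relax `tol`"),
                 maxit, tol, k, n_restarts), call. = FALSE)
  M <- matrix(fit$M, nrow = Tn)   # frames x k component time-courses
  S <- t(matrix(fit$S, nrow = V)) # k x voxels spatial maps (unit variance rows)
  beta <- qr.solve(M, mu)    # refold the voxel-mean time-course into the maps
  resid <- mu - M %*% beta
  if (sqrt(sum(resid^2)) > 1e-6 * max(1, sqrt(sum(mu^2))))
    warning("spatial mean time-course is not fully spanned by the mixing ",
            "matrix; M %*% S reconstruction is approximate", call. = FALSE)
  S <- S + outer(as.vector(beta), rep(1, V))
  ord <- order(fit$vafs, decreasing = TRUE)
  M <- M[, ord, drop = FALSE]; S <- S[ord, , drop = FALSE]
  for (j in seq_len(k)) {      # sign convention: largest-|value| map entry > 0
    i <- which.max(abs(S[j, ]))
    if (S[j, i] < 0) { S[j, ] <- -S[j, ]; M[, j] <- -M[, j] }
  }
  structure(
    list(M = M, S = S, k = as.integer(k),
         iterations = fit$iter, converged = fit$converged,
         seed = as.integer(seed), seed_used = as.integer(seed_used),
         tol = tol, maxit = as.integer(maxit),
         vafs = fit$vafs[ord],
         mask = attr(x_reduced, "mask"),
         frame_interval = attr(x_reduced, "frame_interval")),
    class = "spatial_ica"
  )
}

#' @export
print.spatial_ica <- function(x, ...) {
  cat(sprintf("<spatial_ica> %d components over %d frames x %d voxels (%d iterations, seed %d)\n",
              x$k, nrow(x$M), ncol(x$S), x$iterations, x$seed))
  invisible(x)
}

#' @describeIn run_spatial_ica Component time-courses as a long tibble
#'   (`frame`, `time_s`, `component`, `value`).
#' @export
tidy.spatial_ica <- function(x, ...) {
  Tn <- nrow(x$M)
  dt <- if (is.null(x$frame_interval)) NA_real_ else x$frame_interval
  tibble::tibble(
    frame = rep(seq_len(Tn), x$k),
    time_s = rep(frame_midpoints(Tn, if (is.na(dt)) 1 else dt), x$k),
    component = rep(seq_len(x$k), each = Tn),
    value = as.vector(x$M)
  )
}

#' @describeIn run_spatial_ica One-row fit summary.
#' @export
glance.spatial_ica <- function(x, ...) {
  tibble::tibble(k = x$k, iterations = x$iterations,
                 converged = x$converged, seed = x$seed,
                 n_frames = nrow(x$M), n_voxels = ncol(x$S))
}
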