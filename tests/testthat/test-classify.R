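# minimal hand-built decomposition for classification tests
mock_ica <- function(M, S, mask, frame_interval = 3.8) {
  structure(list(M = M, S = S, k = ncol(M), iterations = 1L, converged = TRUE,
                 seed = 0L, mask = mask, frame_interval = frame_interval),
            class = "spatial_ica")
}

flat_o2sat <- function(n_frames, frame_interval, f = 5e-4, excursion = 3,
                       baseline = 95) {
  tt <- seq(0, ceiling(n_frames * frame_interval), by = 1)
  o2sat_trace(tt, baseline + excursion * sin(2 * pi * f * tt))
}

test_that("pearson_vs_o2sat matches sign symmetry and the t transform", {
  o2 <- flat_o2sat(100, 3.8)
  y <- o2sat_at_frames(o2, 100, 3.8)
  expect_equal(pearson_vs_o2sat(y, o2, 3.8)$r, 1)
  expect_lt(pearson_vs_o2sat(y, o2, 3.8)$p, 1e-12)
  expect_equal(pearson_vs_o2sat(-y, o2, 3.8)$r, -1)
  expect_lt(pearson_vs_o2sat(-y, o2, 3.8)$p, 1e-12)
  # zero-variance input is flagged with p = 1
  res <- pearson_vs_o2sat(rep(1, 100), o2, 3.8)
  expect_true(res$flagged)
  expect_equal(res$p, 1)
})

test_that("t-transform p agrees with a permutation null", {
  set.seed(21)
  n <- 20
  x <- rnorm(n)
  o2 <- flat_o2sat(n, 3.8)
  y <- o2sat_at_frames(o2, n, 3.8)
  res <- pearson_vs_o2sat(x, o2, 3.8)
  robs <- abs(cor(x, y))
  perm <- replicate(10000, abs(cor(x, sample(y))))
  p_perm <- mean(perm >= robs - 1e-12)
  # Monte-Carlo s.e. ~ sqrt(p(1-p)/1e4)
  se <- sqrt(p_perm * (1 - p_perm) / 10000) + 1e-3
  expect_lt(abs(res$p - p_perm), 4 * se + 0.02)
})

test_that("z-thresholding keeps the expected Gaussian tail fraction", {
  set.seed(31)
  keep <- zscore_threshold_map(rnorm(1e4))
  expected <- 2 * (1 - pnorm(2.2))
  expect_lt(abs(mean(keep) - expected),
            4 * sqrt(expected * (1 - expected) / 1e4))
  # an extreme voxel is kept
  m <- c(rnorm(500), 10)
  expect_true(zscore_threshold_map(m)[501])
  # sign symmetry
  expect_identical(as.vector(zscore_threshold_map(m)),
                   as.vector(zscore_threshold_map(-m)))
  # constant map is flagged and empty
  res <- zscore_threshold_map(rep(3, 10))
  expect_true(attr(res, "flagged"))
  expect_false(any(res))
})

test_that("find_clusters matches a brute-force flood fill", {
  # trivial cases
  expect_equal(nrow(find_clusters(array(FALSE, c(4, 4, 2)))), 0L)
  blk <- array(FALSE, c(5, 5, 3)); blk[2:3, 2:3, 1:2] <- TRUE
  cl <- find_clusters(blk)
  expect_equal(cl$size, 8L)
  # seeded random maps against the oracle
  set.seed(41)
  for (i in 1:20) {
    vol <- array(runif(8 * 7 * 4) < 0.35, c(8, 7, 4))
    got <- find_clusters(vol, min_size = 5L)
    want <- flood_fill_clusters(vol, min_size = 5L)
    expect_equal(nrow(got), length(want))
    if (nrow(got)) expect_equal(got$voxels, want)
  }
  # vector-over-mask input places voxels correctly
  mask <- array(TRUE, c(3, 3, 1))
  keep <- rep(FALSE, 9); keep[1:5] <- TRUE
  expect_equal(find_clusters(keep, mask = mask, min_size = 2L)$size, 5L)
})

test_that("distinctiveness separates slow oscillations from white noise", {
  tt <- (seq_len(947) - 0.5) * 3.8
  expect_gt(distinctiveness(sin(2 * pi * 8e-4 * tt)), 0.9)
  set.seed(51)
  scores <- replicate(100, abs(distinctiveness(rnorm(947))))
  expect_gte(sum(scores < 0.3), 95L)
  expect_true(is.na(distinctiveness(rep(2, 100))))
})

test_that("components are classified by the three-way decision rule", {
  n <- 400; dt <- 3.8
  o2 <- flat_o2sat(n, dt)
  y <- o2sat_at_frames(o2, n, dt)
  mask <- array(TRUE, c(10, 10, 1))
  set.seed(61)
  # comp 1: O2sat copy; comp 2: oscillator in a 10-voxel blob (two criteria);
  # comp 3: diffuse white noise
  tt <- (seq_len(n) - 0.5) * dt
  m2 <- sin(2 * pi * 8e-4 * tt)
  m3 <- rnorm(n)
  blob <- rep(0, 100); blob[c(44:48, 54:58)] <- 5
  S <- rbind(rexp(100), blob + rnorm(100, sd = 0.05), rnorm(100))
  M <- cbind(scale(y), m2, m3)
  labs <- classify_components(mock_ica(M, S, mask), o2)
  expect_equal(labs$class, c("systemic", "tumour_specific", "noise"))
  expect_true(labs$peak[2])
  expect_gte(labs$n_clusters[2], 1L)
  # sign flip of any component leaves labels unchanged
  M2 <- M; S2 <- S
  M2[, 2] <- -M2[, 2]; S2[2, ] <- -S2[2, ]
  labs2 <- classify_components(mock_ica(M2, S2, mask), o2)
  expect_equal(labs2$class, labs$class)
  # raising the systemic threshold only grows the systemic set
  sets <- lapply(c(1e-8, 0.01, 0.9), function(a)
    which(classify_components(mock_ica(M, S, mask), o2,
                              p_systemic = a)$class == "systemic"))
  expect_true(all(sets[[1]] %in% sets[[2]]))
  expect_true(all(sets[[2]] %in% sets[[3]]))
})

test_that("class reconstructions are additive and complete", {
  ph <- generate_phantom(small_config(seed = 6))
  pca <- pca_decompose(ph$series)
  red <- reduce_series(pca, select_eigenvectors(pca))
  ica <- run_spatial_ica(red, seed = 0)
  labs <- classify_components(ica, ph$o2sat)
  MS <- ica$M %*% ica$S
  total <- reconstruct_class(ica, labs, "systemic") +
    reconstruct_class(ica, labs, "tumour_specific") +
    reconstruct_class(ica, labs, "noise")
  expect_lt(norm(total - MS, "F") / norm(MS, "F"), 1e-10)
  # empty class gives a zero field
  none <- labs; none$class <- "noise"
  expect_true(all(reconstruct_class(ica, none, "systemic") == 0))
  # single class reproduces M S exactly
  all_sys <- labs; all_sys$class <- "systemic"
  expect_equal(reconstruct_class(ica, all_sys, "systemic"), MS)
})

test_that("voxel thresholding recovers noiseless truth regions", {
  # bounded (uniform) gains: every systemic voxel carries detectable signal
  cfg <- medium_config(noise_sd = 0, seed = 7, o2sat_noise_sd = 0.1,
                       systemic_gain_dist = "uniform")
  ph <- generate_phantom(cfg)
  pca <- pca_decompose(ph$series)
  red <- reduce_series(pca, select_eigenvectors(pca))
  ica <- run_spatial_ica(red, seed = 0)
  labs <- classify_components(ica, ph$o2sat)
  fl <- threshold_voxels(ica, labs, ph$o2sat, ph$series)
  mask <- ph$series$mask
  acc_sys <- mean(fl$systemic_mask[mask] == ph$truth_systemic[mask])
  acc_tsp <- mean(fl$tumour_specific_mask[mask] == ph$truth_tumour_specific[mask])
  expect_gte(acc_sys, 0.99)
  expect_gte(acc_tsp, 0.99)
})

test_that("overlapping sources appear in both voxel masks", {
  # the iid systemic draw places systemic signal inside the cluster too
  cfg <- medium_config(noise_sd = 0, seed = 8, o2sat_noise_sd = 0.1,
                       systemic_gain_dist = "uniform")
  ph <- generate_phantom(cfg)
  overlap <- ph$truth_systemic & ph$truth_tumour_specific
  expect_gt(sum(overlap), 0)
  pca <- pca_decompose(ph$series)
  red <- reduce_series(pca, select_eigenvectors(pca))
  ica <- run_spatial_ica(red, seed = 0)
  labs <- classify_components(ica, ph$o2sat)
  fl <- threshold_voxels(ica, labs, ph$o2sat, ph$series)
  expect_gte(mean(fl$systemic_mask[overlap]), 0.9)
  expect_gte(mean(fl$tumour_specific_mask[overlap]), 0.9)
})

test_that("a class with no components yields an empty voxel mask", {
  ph <- generate_phantom(small_config(seed = 9))
  pca <- pca_decompose(ph$series)
  red <- reduce_series(pca, select_eigenvectors(pca))
  ica <- run_spatial_ica(red, seed = 0)
  labs <- classify_components(ica, ph$o2sat)
  labs$class <- "noise"
  fl <- threshold_voxels(ica, labs, ph$o2sat, ph$series)
  expect_equal(sum(fl$systemic_mask), 0)
  expect_equal(sum(fl$tumour_specific_mask), 0)
})
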