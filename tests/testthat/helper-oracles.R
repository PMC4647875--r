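# Independent oracles and small fixtures shared across the suite.

# Brute-force flood fill over a 3D logical array: queue-based BFS, written
# independently of the igraph route used by find_clusters().
flood_fill_clusters <- function(vol, min_size = 5L, connectivity = 6L) {
  d <- dim(vol)
  offs <- switch(as.character(connectivity),
    "6" = rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1)),
    "26" = {
      g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
      g[rowSums(abs(g)) > 0, , drop = FALSE]
    })
  seen <- array(FALSE, d)
  clusters <- list()
  for (start in which(vol & !seen)) {
    if (seen[start]) next
    queue <- start; seen[start] <- TRUE; members <- integer(0)
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      members <- c(members, cur)
      cc <- arrayInd(cur, d)
      for (r in seq_len(nrow(offs))) {
        nb <- cc + offs[r, , drop = FALSE]
        if (any(nb < 1) || any(nb > d)) next
        li <- nb[1] + (nb[2] - 1) * d[1] + (nb[3] - 1) * d[1] * d[2]
        if (vol[li] && !seen[li]) { seen[li] <- TRUE; queue <- c(queue, li) }
      }
    }
    if (length(members) >= min_size) clusters[[length(clusters) + 1L]] <- sort(as.integer(members))
  }
  clusters[order(-vapply(clusters, length, integer(1)))]
}

# Exact two-sided signed-rank p by direct enumeration of all 2^n sign
# vectors (definition-level, no convolution).
wilcoxon_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  wobs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  wall <- signs %*% rk
  min(1, 2 * min(mean(wall <= wobs + 1e-9), mean(wall >= wobs - 1e-9)))
}

# Exact two-sided Mann-Whitney p by enumeration of all group labelings.
mann_whitney_enum_p <- function(a, b) {
  na <- length(a); n <- na + length(b)
  rk <- rank(c(a, b))
  uobs <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  uall <- apply(combn(n, na), 2, function(ix) sum(rk[ix]) - na * (na + 1) / 2)
  min(1, 2 * min(mean(uall <= uobs + 1e-9), mean(uall >= uobs - 1e-9)))
}

balanced_accuracy <- function(pred, truth, mask) {
  p <- pred[mask]; t <- truth[mask]
  (mean(p[t]) + mean(!p[!t])) / 2
}

# Medium phantom for voxel-recovery geometry tests: large enough that a
# compact cluster is a small fraction of the mask, keeping the intrinsic
# correlation between a contiguous systemic region and the cluster map small.
medium_config <- function(...) {
  args <- utils::modifyList(
    list(grid_shape = c(24L, 24L, 4L),
         mask_semiaxes = c(9, 9, 1.7),
         n_frames = 240L,
         clusters = tibble::tibble(x = 16, y = 12, z = 2, radius = 2,
                                   amplitude = 0.01)),
    list(...))
  do.call(phantom_config, args)
}

# Small, fast phantom used by module-level tests (~180 mask voxels).
small_config <- function(...) {
  args <- utils::modifyList(
    list(grid_shape = c(16L, 16L, 3L),
         mask_semiaxes = c(6, 6, 1.2),
         n_frames = 240L,
         clusters = tibble::tibble(x = 11, y = 8, z = 2, radius = 2,
                                   amplitude = 0.01)),
    list(...), keep.null = TRUE)
  do.call(phantom_config, args)
}
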