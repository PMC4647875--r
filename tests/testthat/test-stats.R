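test_that("exact signed-rank p-values for the five-pair configurations", {
  # one discordant pair whose magnitude ranks smallest
  expect_equal(wilcoxon_signed_exact(c(-1, 2, 3, 4, 5))$p.value, 0.125)
  # one discordant pair whose magnitude ranks third smallest
  expect_equal(wilcoxon_signed_exact(c(1, 2, -3, 4, 5))$p.value, 0.3125)
  # all five concordant: the smallest attainable two-sided value, 2/32
  expect_equal(wilcoxon_signed_exact(c(1, 2, 3, 4, 5))$p.value, 0.0625)
  res <- wilcoxon_signed_exact(c(-1, 2, 3, 4, 5))
  expect_true(res$exact)
  expect_equal(res$statistic, 1)
  expect_equal(res$n, 5L)
})

test_that("exact signed-rank agrees with full 2^n enumeration and wilcox.test", {
  set.seed(81)
  for (i in 1:60) {
    n <- sample(2:10, 1)
    d <- round(rnorm(n), 2)
    d[d == 0] <- 0.01
    p_pkg <- wilcoxon_signed_exact(d)$p.value
    expect_equal(p_pkg, wilcoxon_enum_p(d), tolerance = 1e-12)
    # against R's exact test when magnitudes are untied
    if (!any(duplicated(abs(d))))
      expect_equal(p_pkg,
                   suppressWarnings(wilcox.test(d, exact = TRUE)$p.value),
                   tolerance = 1e-12)
    # exact p is rational with denominator 2^n
    expect_equal(p_pkg * 2^n, round(p_pkg * 2^n), tolerance = 1e-8)
  }
})

test_that("signed-rank handles zeros, ties and large n", {
  expect_message(res <- wilcoxon_signed_exact(c(0, 1, 2, 3)), "zero difference")
  expect_equal(res$n, 3L)
  expect_warning(r0 <- wilcoxon_signed_exact(c(0, 0)), "all differences")
  expect_equal(r0$p.value, 1)
  expect_true(r0$flagged)
  # beyond the enumeration budget: normal approximation, sane p
  set.seed(82)
  d <- rnorm(50, mean = 0.3)
  res <- wilcoxon_signed_exact(d)
  expect_false(res$exact)
  expect_equal(res$p.value,
               suppressWarnings(wilcox.test(d, correct = FALSE)$p.value),
               tolerance = 1e-6)
  # invariance under negation
  set.seed(83)
  d <- rnorm(8)
  expect_equal(wilcoxon_signed_exact(d)$p.value,
               wilcoxon_signed_exact(-d)$p.value)
})

test_that("Mann-Whitney exact p matches labeling enumeration", {
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 2 / 6, tolerance = 1e-12)
  expect_true(res$exact)
  # identical groups: p = 1
  expect_equal(mann_whitney_u(c(5, 5, 5), c(5, 5, 5))$p.value, 1)
  # the histology comparison sizes: 5 vs 4, against C(9,5) enumeration
  set.seed(84)
  for (i in 1:30) {
    a <- rnorm(5); b <- rnorm(4, mean = runif(1, -1, 1))
    p_pkg <- mann_whitney_u(a, b)$p.value
    expect_equal(p_pkg, mann_whitney_enum_p(a, b), tolerance = 1e-12)
    expect_equal(p_pkg * choose(9, 5), round(p_pkg * choose(9, 5)),
                 tolerance = 1e-6)
    if (!any(duplicated(c(a, b))))
      expect_equal(p_pkg, wilcox.test(a, b, exact = TRUE)$p.value,
                   tolerance = 1e-12)
  }
  # negation invariance
  a <- c(0.3, 1.2, -0.5, 2); b <- c(0.1, -0.7, 1.5)
  expect_equal(mann_whitney_u(a, b)$p.value, mann_whitney_u(-a, -b)$p.value)
})

test_that("Spearman's rho is rank-then-Pearson with exact small-n p", {
  x <- c(1, 3, 5, 7, 9, 11)
  expect_equal(spearman_rho(x, x^3)$estimate, 1)
  expect_equal(spearman_rho(x, -sqrt(x))$estimate, -1)
  set.seed(85)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(spearman_rho(x, y)$estimate, cor(rank(x), rank(y)),
               tolerance = 1e-12)
  # exact permutation p at n = 6 against direct enumeration
  x6 <- rnorm(6); y6 <- rnorm(6)
  res <- spearman_rho(x6, y6)
  expect_true(res$exact)
  perms <- hypoxica:::permutations_of(6L)
  rho_obs <- cor(rank(x6), rank(y6))
  rho_all <- apply(perms, 1, function(pm) cor(rank(x6), rank(y6)[pm]))
  expect_equal(res$p.value, mean(abs(rho_all) >= abs(rho_obs) - 1e-12),
               tolerance = 1e-12)
  # constant input flagged
  expect_warning(rc <- spearman_rho(rep(1, 5), rnorm(5)), "constant")
  expect_true(rc$flagged)
})

test_that("pearson_t_p implements the r -> t -> p transform", {
  x <- rnorm(30)
  expect_equal(pearson_t_p(x, x)$p.value, 0)
  expect_equal(pearson_t_p(x, x)$estimate, 1)
  set.seed(86)
  x <- rnorm(25); y <- rnorm(25)
  res <- pearson_t_p(x, y)
  ct <- cor.test(x, y)
  expect_equal(res$p.value, ct$p.value, tolerance = 1e-10)
  expect_equal(res$estimate, unname(ct$estimate), tolerance = 1e-12)
  # negation invariance (two-sided)
  expect_equal(pearson_t_p(x, -y)$p.value, res$p.value)
  expect_warning(rf <- pearson_t_p(rep(1, 10), rnorm(10)), "zero-variance")
  expect_equal(rf$p.value, 1)
})

test_that("null p-values are uniform", {
  set.seed(87)
  ps <- replicate(2000, pearson_t_p(rnorm(50), rnorm(50))$p.value)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
})
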