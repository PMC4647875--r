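# Exact small-sample nonparametrics. With five tumours per line, normal
# approximations to rank tests are invalid; p-values are computed by full
# enumeration (2^n sign assignments, C(na+nb, na) labelings, n! rank
# permutations) whenever the enumeration is affordable, and by the standard
# tie-corrected normal / t approximations otherwise.
#
# Two-sided convention for exact tests: p = min(1, 2 * min(P(T <= t), P(T >= t))),
# each tail including the observed point. Conventions differ across software;
# this one is symmetric and never anti-conservative by construction.

test_result <- function(statistic, p, method, exact, n, estimate = NA_real_,
                        flagged = FALSE) {
  tibble::tibble(statistic = statistic, p.value = min(1, p), method = method,
                 exact = exact, n = n, estimate = estimate, flagged = flagged)
}

#' Pearson correlation with t-transform p-value
#'
#' Pearson's r transformed to t = r sqrt((n - 2) / (1 - r^2)) on n - 2
#' degrees of freedom, two-sided.
#'
#' @param x,y Equal-length numeric vectors, length >= 4.
#' @return One-row tibble: `statistic` (t), `p.value`, `method`, `exact`,
#'   `n`, `estimate` (r), `flagged`.
#' @export
pearson_t_p <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 4L) stop("need equal lengths >= 4", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero-variance input: correlation undefined", call. = FALSE)
    return(test_result(NA_real_, 1, "pearson_t", FALSE, n, flagged = TRUE))
  }
  r <- cor(x, y)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- if (abs(r) >= 1) 0 else 2 * pt(-abs(tt), df = n - 2)
  test_result(tt, p, "pearson_t", FALSE, n, estimate = r)
}

# distribution of 2*W+ over all 2^n equally likely sign assignments,
# by convolution over the (doubled, hence integer) ranks
signed_rank_distribution <- function(ranks2) {
  total <- sum(ranks2)
  f <- numeric(total + 1L)  # index i <-> value i - 1
  f[1L] <- 1
  for (r in ranks2) {
    g <- numeric(total + 1L)
    g[seq_len(total + 1L - r) + r] <- f[seq_len(total + 1L - r)]
    f <- f + g
  }
  f / sum(f)
}

#' Exact Wilcoxon matched-pairs signed-rank test
#'
#' Signed-rank test on paired differences with exact two-sided p-value by
#' full enumeration of all 2^n sign assignments for n <= `exact_limit`
#' (enumerated via rank-sum convolution), and the tie-corrected normal
#' approximation beyond. Zero differences are dropped (with a message); tied
#' magnitudes receive mid-ranks. The statistic is W = min(W+, W-).
#'
#' @param differences Paired differences.
#' @param exact_limit Largest n (after dropping zeros) for exact enumeration.
#' @return One-row tibble: `statistic` (W), `p.value`, `method`, `exact`,
#'   `n` (non-zero pairs), `flagged`.
#' @examples
#' # four positive differences, one negative of smallest magnitude: p = 0.125
#' wilcoxon_signed_exact(c(-1, 2, 3, 4, 5))
#' @export
wilcoxon_signed_exact <- function(differences, exact_limit = 20L) {
  d <- differences[!is.na(differences)]
  nz <- d != 0
  if (any(!nz)) message(sum(!nz), " zero difference(s) dropped")
  d <- d[nz]
  n <- length(d)
  if (n == 0L) {
    warning("all differences are zero", call. = FALSE)
    return(test_result(NA_real_, 1, "wilcoxon_signed_rank", TRUE, 0L, flagged = TRUE))
  }
  if (n < 2L) stop("need >= 2 non-zero differences", call. = FALSE)
  rk <- rank(abs(d))
  wplus <- sum(rk[d > 0])
  wminus <- n * (n + 1) / 2 - wplus
  W <- min(wplus, wminus)
  if (n <= exact_limit) {
    dist <- signed_rank_distribution(as.integer(round(2 * rk)))
    w2 <- as.integer(round(2 * wplus))
    lower <- sum(dist[seq_len(w2 + 1L)])
    upper <- sum(dist[(w2 + 1L):length(dist)])
    p <- 2 * min(lower, upper)
    test_result(W, p, "wilcoxon_signed_rank", TRUE, n)
  } else {
    ties <- table(rk)
    mu <- n * (n + 1) / 4
    sig <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48)
    z <- (wplus - mu) / sig
    test_result(W, 2 * pnorm(-abs(z)), "wilcoxon_signed_rank_normal", FALSE, n)
  }
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent groups. The exact two-sided
#' p-value enumerates all choose(na + nb, na) group labelings when
#' na + nb <= `exact_limit` (valid under ties, which receive mid-ranks); the
#' tie-corrected normal approximation is used beyond. The statistic is
#' U = min(Ua, Ub).
#'
#' @param a,b Numeric vectors, both non-empty.
#' @param exact_limit Largest combined size for exact enumeration.
#' @return One-row tibble: `statistic` (U), `p.value`, `method`, `exact`, `n`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # U = 0, p = 1/3
#' @export
mann_whitney_u <- function(a, b, exact_limit = 12L) {
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) stop("both groups must be non-empty", call. = FALSE)
  rk <- rank(c(a, b))
  ua <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  ub <- na * nb - ua
  U <- min(ua, ub)
  n <- na + nb
  if (n <= exact_limit) {
    picks <- combn(n, na)
    uvals <- apply(picks, 2L, function(ix) sum(rk[ix]) - na * (na + 1) / 2)
    eps <- 1e-9
    lower <- mean(uvals <= ua + eps)
    upper <- mean(uvals >= ua - eps)
    p <- 2 * min(lower, upper)
    test_result(U, p, "mann_whitney_u", TRUE, n)
  } else {
    mu <- na * nb / 2
    ties <- table(rk)
    sig <- sqrt(na * nb / 12 * (n + 1 - sum(ties^3 - ties) / (n * (n - 1))))
    z <- (ua - mu) / sig
    test_result(U, 2 * pnorm(-abs(z)), "mann_whitney_u_normal", FALSE, n)
  }
}

# all permutations of 1..n (n <= 8 in practice)
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks. For n <= `exact_limit` with untied data
#' the two-sided p-value is exact, from full enumeration of all n! rank
#' permutations (P(|rho| >= observed)); otherwise the t approximation on
#' n - 2 degrees of freedom is used.
#'
#' @param x,y Equal-length numeric vectors, length >= 4.
#' @param exact_limit Largest n for exact permutation enumeration.
#' @return One-row tibble: `statistic` (rho), `p.value`, `method`, `exact`,
#'   `n`, `estimate` (rho), `flagged`.
#' @export
spearman_rho <- function(x, y, exact_limit = 8L) {
  n <- length(x)
  if (length(y) != n || n < 4L) stop("need equal lengths >= 4", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant input: rank correlation undefined", call. = FALSE)
    return(test_result(NA_real_, 1, "spearman_rho", FALSE, n, flagged = TRUE))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  no_ties <- !anyDuplicated(rx) && !anyDuplicated(ry)
  if (n <= exact_limit && no_ties) {
    perms <- permutations_of(n)
    rhos <- apply(perms, 1L, function(pm) cor(rx, ry[pm]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    test_result(rho, p, "spearman_rho", TRUE, n, estimate = rho)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- if (abs(rho) >= 1) 0 else 2 * pt(-abs(tt), df = n - 2)
    test_result(rho, p, "spearman_rho_t", FALSE, n, estimate = rho)
  }
}
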