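# Independent brute-force oracles --------------------------------------------

# 2x2 Fisher by direct enumeration over the hypergeometric support.
fisher_oracle_2x2 <- function(m) {
  rs <- rowSums(m); cs <- colSums(m)
  k <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
  probs <- dhyper(k, rs[1], rs[2], cs[1])
  obs <- dhyper(m[1, 1], rs[1], rs[2], cs[1])
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# 2x3 Fisher by enumerating both free cells of the first row.
fisher_oracle_2x3 <- function(m) {
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  prob_table <- function(a, b) {
    cc <- rs[1] - a - b
    if (cc < 0 || a > cs[1] || b > cs[2] || cc > cs[3]) return(0)
    choose(cs[1], a) * choose(cs[2], b) * choose(cs[3], cc) / choose(n, rs[1])
  }
  obs <- prob_table(m[1, 1], m[1, 2])
  total <- 0
  for (a in 0:min(rs[1], cs[1])) {
    for (b in 0:min(rs[1] - a, cs[2])) {
      p <- prob_table(a, b)
      if (p > 0 && p <= obs * (1 + 1e-7)) total <- total + p
    }
  }
  total
}

# Exact two-sided rank-sum p by enumerating all group assignments.
wilcoxon_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- combn(length(pooled), n1)
  w_all <- apply(combs, 2, function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
  p_low <- mean(w_all <= w_obs)
  p_high <- mean(w_all >= w_obs)
  min(1, 2 * min(p_low, p_high))
}

# -----------------------------------------------------------------------------

test_that("BH adjustment matches a hand-rolled step-up and is monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))

  step_up <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- rev(cummin(rev(m * p[o] / seq_len(m))))
    pmin(adj, 1)[order(o)]
  }
  set.seed(5)
  for (i in 1:5) {
    p <- runif(20)
    adj <- bh_adjust(p)
    expect_equal(adj, step_up(p))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    expect_true(all(adj >= p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("2x2 Fisher reproduces the analytic value and the enumeration oracle", {
  m <- matrix(c(19, 2, 0, 12), 2, 2, byrow = TRUE)
  p <- fisher_exact_2x2(m)
  expect_equal(p, 210 / 818809200, tolerance = 1e-10)
  expect_equal(signif(p, 2), 2.6e-07)

  expect_equal(fisher_exact_2x2(matrix(1, 2, 2)), 1)
  # symmetry under row swap, column swap, transpose
  expect_equal(fisher_exact_2x2(m[2:1, ]), p)
  expect_equal(fisher_exact_2x2(m[, 2:1]), p)
  expect_equal(fisher_exact_2x2(t(m)), p)
  # zero margin
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)), 1)

  set.seed(9)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 4), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab), fisher_oracle_2x2(tab), tolerance = 1e-10)
  }
})

test_that("r x c Fisher enumerates margins and collapses degenerate tables", {
  m3 <- matrix(c(10, 11, 5, 2, 4, 1), 3, 2, byrow = TRUE)
  p <- fisher_exact_rxc(m3)
  expect_equal(fisher_oracle_2x3(t(m3)), p, tolerance = 1e-10)
  expect_lt(abs(p - 0.34), 0.0075) # agrees with the printed two-decimal value

  # 2x2 consistency
  m <- matrix(c(3, 5, 6, 2), 2, 2)
  expect_equal(fisher_exact_rxc(m), fisher_exact_2x2(m), tolerance = 1e-12)
  # an all-zero column collapses to the reduced table
  m23 <- cbind(m, c(0, 0))
  expect_equal(fisher_exact_rxc(m23), fisher_exact_2x2(m), tolerance = 1e-12)

  big <- matrix(c(100, 50, 60, 90, 40, 70), 2, 3)
  expect_error(fisher_exact_rxc(big), "enumeration limit")
  p_mc <- fisher_exact_rxc(big, monte_carlo = TRUE, n_sim = 2000, seed = 4)
  expect_true(p_mc > 0 && p_mc <= 1)
})

test_that("chi-square with continuity correction reproduces printed values", {
  tab <- matrix(c(917, 78, 24022, 2826), 2, 2, byrow = TRUE)
  res <- chi_square(tab)
  expect_equal(round(res$p, 3), 0.008)
  expect_equal(res$df, 1)

  # observed equal to expected: statistic 0, p 1
  even <- matrix(c(10, 20, 10, 20), 2, 2, byrow = TRUE)
  res0 <- chi_square(even)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)

  # large counts: asymptotic agreement with the exact test
  big <- matrix(c(100, 80, 80, 110), 2, 2)
  p_chi <- chi_square(big)$p
  p_fish <- fisher_exact_2x2(big)
  expect_lt(abs(p_chi - p_fish) / p_fish, 0.2)

  r3 <- chi_square(matrix(c(5, 10, 15, 10, 10, 10), 2, 3, byrow = TRUE))
  expect_equal(r3$df, 2)
  expect_error(chi_square(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)), "zero margin")
})

test_that("rank-sum test switches between exact enumeration and approximation", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4)), 1 / 3, tolerance = 1e-12)
  # identical samples (full ties): approximation path, p = 1
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3)), 1)

  set.seed(21)
  for (i in 1:3) {
    vals <- sample(1000, 12) # distinct values so the exact path is taken
    x <- vals[1:6]
    y <- vals[7:12]
    expect_equal(wilcoxon_rank_sum(x, y), wilcoxon_oracle(x, y), tolerance = 1e-12)
  }
  # above the exact threshold the approximation is used and stays in (0,1]
  x <- rnorm(20); y <- rnorm(20) + 0.2
  p <- wilcoxon_rank_sum(x, y)
  expect_true(p > 0 && p <= 1)
})

test_that("Kruskal-Wallis matches the closed form on separated ranks", {
  groups <- list(1:5, 6:10, 11:15)
  res <- kruskal_wallis(groups)
  expect_equal(res$H, 12.5, tolerance = 1e-12) # 12/(15*16)*sum(R_j^2/5) - 48
  expect_equal(res$df, 2)
  expect_lt(res$p, 0.01)

  # all observations equal: H = 0, p = 1 by convention
  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2)))$H, 0)
  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2)))$p, 1)

  # two-group identity: H equals the squared rank-sum z (no continuity corr.)
  set.seed(8)
  x <- rnorm(9); y <- rnorm(7) + 0.5
  res2 <- kruskal_wallis(list(x, y))
  r <- rank(c(x, y))
  n1 <- 9; n <- 16
  w <- sum(r[1:9])
  z <- (w - n1 * (n + 1) / 2) / sqrt(n1 * 7 * (n + 1) / 12)
  expect_equal(res2$H, z^2, tolerance = 1e-9)

  expect_error(kruskal_wallis(list(1:3)), "two groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "empty")
})

test_that("Spearman correlation uses mid-ranks and exact small-n permutation", {
  x <- 1:8
  expect_equal(spearman_cor(x, rev(x))$r, -1)
  expect_equal(spearman_cor(x, exp(x))$r, 1) # monotone-transform invariance

  # n = 5: p equals the 120-permutation enumeration (cor.test exact, no ties)
  set.seed(14)
  for (i in 1:3) {
    a <- sample(100, 5); b <- sample(100, 5)
    got <- spearman_cor(a, b)
    ref <- cor.test(a, b, method = "spearman")
    expect_equal(got$r, unname(ref$estimate))
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }

  # mid-ranks under ties match the standard rank correlation
  a <- c(1, 2, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11)
  b <- c(2, 1, 4, 4, 5, 7, 6, 9, 8, 11, 10, 12)
  expect_equal(spearman_cor(a, b)$r, cor(a, b, method = "spearman"))

  expect_error(spearman_cor(c(1, 1, 1), c(1, 2, 3)), "rank variance")
  expect_error(spearman_cor(1:2, 2:1), "n >= 3")
})

test_that("Stouffer combination is signed, normalized, and handles edge cases", {
  one <- stouffer_combine(0.04, 1)
  expect_equal(one$p, 0.04, tolerance = 1e-12)

  z <- qnorm(1 - 0.10 / 2) # 1.6449
  two <- stouffer_combine(c(0.10, 0.10), c(1, 1))
  expect_equal(two$z, 2 * z / sqrt(2), tolerance = 1e-12)
  expect_equal(two$z, 2.3263, tolerance = 1e-3)

  cancel <- stouffer_combine(c(0.05, 0.05), c(1, -1))
  expect_equal(cancel$z, 0)
  expect_equal(cancel$p, 1)

  expect_warning(res <- stouffer_combine(c(0, 0.5), c(1, 1)), "clipped")
  expect_true(res$p > 0)
  expect_error(stouffer_combine(0.5, 2), "signs")
})
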