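# Shared statistical primitives. These delegate to the standard base-R
# implementations (p.adjust, fisher.test, chisq.test, wilcox.test,
# kruskal.test) behind a uniform interface; only the small-sample Spearman
# permutation p-value is computed in-package because the base exact code
# does not accept ties.

#' Benjamini-Hochberg adjustment
#'
#' @param p Numeric vector of p-values in \[0,1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

as_contingency <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0) || any(x != round(x))) stop("contingency table must hold nonnegative integers")
  if (nrow(x) < 2 || ncol(x) < 2) stop("contingency table must be at least 2x2")
  storage.mode(x) <- "integer"
  x
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value under the probability-mass definition: the sum of
#' hypergeometric probabilities of all tables with the observed margins whose
#' probability does not exceed that of the observed table (with a small
#' relative tolerance on the comparison).
#'
#' @param x 2x2 matrix of nonnegative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(x) {
  x <- as_contingency(x)
  if (!all(dim(x) == 2)) stop("fisher_exact_2x2 expects a 2x2 table")
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) return(1)
  stats::fisher.test(x)$p.value
}

#' Fisher's exact test on an r x c table
#'
#' Exact enumeration over all tables with the observed margins. For totals
#' above `total_max` the exact computation is refused unless `monte_carlo` is
#' set, in which case a seeded Monte-Carlo estimate (flagged approximate) is
#' returned.
#'
#' @param x r x c matrix of nonnegative integer counts.
#' @param total_max Enumeration limit on the grand total (default 200).
#' @param monte_carlo Use Monte-Carlo approximation above the limit.
#' @param n_sim Number of Monte-Carlo tables.
#' @param seed Seed for the Monte-Carlo path.
#' @return Two-sided p-value.
#' @export
fisher_exact_rxc <- function(x, total_max = 200, monte_carlo = FALSE,
                             n_sim = 1e5, seed = 1) {
  x <- as_contingency(x)
  # collapse all-zero rows/columns (they carry no information)
  x <- x[rowSums(x) > 0, colSums(x) > 0, drop = FALSE]
  if (nrow(x) < 2 || ncol(x) < 2) return(1)
  if (all(dim(x) == 2)) return(fisher_exact_2x2(x))
  if (sum(x) > total_max) {
    if (!monte_carlo) {
      stop("table total ", sum(x), " exceeds the enumeration limit (",
           total_max, "); set monte_carlo = TRUE for a seeded approximation")
    }
    set.seed(seed)
    return(stats::fisher.test(x, simulate.p.value = TRUE, B = n_sim)$p.value)
  }
  stats::fisher.test(x)$p.value
}

#' Chi-square test of independence
#'
#' @param x Contingency table (matrix of counts).
#' @param yates Apply the continuity correction (only used for 2x2 tables);
#'   default `TRUE`.
#' @return List with `statistic`, `df`, and `p`.
#' @export
chi_square <- function(x, yates = TRUE) {
  x <- as_contingency(x)
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    stop("chi-square test undefined for tables with a zero margin")
  }
  correct <- isTRUE(yates) && all(dim(x) == 2)
  res <- suppressWarnings(stats::chisq.test(x, correct = correct))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Wilcoxon rank-sum test
#'
#' Exact enumeration when both samples have at most `exact_max_n`
#' observations and there are no ties; otherwise the normal approximation
#' with tie and continuity correction (p capped at 1).
#'
#' @param x,y Numeric samples.
#' @param exact_max_n Size threshold for the exact path (default 8).
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max_n = 8) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be nonempty")
  # every pooled observation tied: no evidence either way
  if (length(unique(c(x, y))) == 1) return(1)
  exact <- length(x) <= exact_max_n && length(y) <= exact_max_n &&
    !any(duplicated(c(x, y)))
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
  )
  min(p, 1)
}

#' Kruskal-Wallis test
#'
#' @param groups List of numeric samples (>= 2 groups, each nonempty).
#' @return List with `H` (tie-corrected statistic), `df`, and `p`. When every
#'   observation is identical the statistic is 0 and p = 1 by convention.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least two groups")
  if (any(vapply(groups, length, integer(1)) == 0)) stop("empty group")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  if (length(values) < 3) stop("need total n >= 3")
  if (length(unique(values)) == 1) {
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  }
  res <- stats::kruskal.test(values, g)
  list(H = unname(res$statistic), df = unname(res$parameter), p = res$p.value)
}

# All permutations of 1..n (n <= 9), as an n! x n matrix.
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    rest <- seq_len(n)[-i]
    out[rows, 1] <- i
    out[rows, -1] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

#' Spearman rank correlation
#'
#' Correlation of mid-ranks. The p-value uses the t-distribution
#' approximation for n >= 10 and an exact permutation enumeration (over all
#' n! orderings, mid-ranks for ties) for n < 10.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return List with `r` and `p`.
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length")
  if (n < 3) stop("need n >= 3")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    stop("rank variance is zero; Spearman correlation undefined")
  }
  r <- stats::cor(rx, ry)
  if (n >= 10) {
    tval <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  } else {
    perms <- permutations_of(n)
    r_perm <- apply(perms, 1, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(r_perm) >= abs(r) - 1e-12)
  }
  list(r = r, p = min(p, 1))
}
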