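# Methylation-expression integration and cross-comparison overlap statistics:
# probe-group mean beta, Spearman correlation against expression with the
# significant-negative rule, DMP-set overlap/concordance, Venn partitions,
# and a database-agnostic hypergeometric over-representation test.

#' Average beta over probe groups
#'
#' @param betas Beta matrix.
#' @param groups Named list: feature (gene or region) -> probe ids.
#' @return Features-by-samples matrix of mean beta. Features with no
#'   surviving probes are dropped with a warning.
#' @export
probe_group_mean_beta <- function(betas, groups) {
  if (length(groups) == 0) stop("groups must be nonempty")
  keep <- vapply(groups, function(p) any(p %in% rownames(betas)), logical(1))
  if (any(!keep)) {
    warning("dropping feature(s) with no surviving probes: ",
            paste(utils::head(names(groups)[!keep], 5), collapse = ", "))
  }
  groups <- groups[keep]
  out <- matrix(NA_real_, length(groups), ncol(betas),
                dimnames = list(names(groups), colnames(betas)))
  for (i in seq_along(groups)) {
    out[i, ] <- colMeans(betas[intersect(groups[[i]], rownames(betas)), ,
                               drop = FALSE])
  }
  out
}

#' Correlate feature methylation with gene expression
#'
#' Spearman correlation of each feature's mean beta against the expression of
#' its gene over the shared samples, BH adjustment across all tested
#' features, and the significance rule: a feature is `significant_negative`
#' when its correlation is negative with adjusted p < 0.05.
#'
#' @param mean_beta Features-by-samples matrix (e.g. from
#'   [probe_group_mean_beta()]).
#' @param expression Genes-by-samples expression matrix.
#' @param feature_gene_map Optional named character vector feature -> gene;
#'   by default features are assumed to be gene names.
#' @param min_shared Minimum shared samples per feature (default 3).
#' @return `MethExprResult` data frame: feature, gene, n_samples, spearman_r,
#'   p_raw, p_adj, significant_negative.
#' @export
meth_expr_correlation <- function(mean_beta, expression,
                                  feature_gene_map = NULL, min_shared = 3) {
  features <- rownames(mean_beta)
  genes <- if (is.null(feature_gene_map)) {
    stats::setNames(features, features)
  } else feature_gene_map
  shared <- intersect(colnames(mean_beta), colnames(expression))
  rows <- lapply(features, function(f) {
    g <- genes[[f]]
    if (is.null(g) || !g %in% rownames(expression)) {
      message("gene for feature '", f, "' absent from expression matrix; skipped")
      return(NULL)
    }
    x <- mean_beta[f, shared]
    y <- expression[g, shared]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < min_shared) return(NULL)
    sp <- tryCatch(spearman_cor(x[ok], y[ok]), error = function(e) NULL)
    if (is.null(sp)) return(NULL)
    data.frame(feature = f, gene = g, n_samples = sum(ok),
               spearman_r = sp$r, p_raw = sp$p, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(rows) || nrow(rows) == 0) {
    stop("no feature could be tested against expression")
  }
  rows$p_adj <- bh_adjust(rows$p_raw)
  rows$significant_negative <- rows$spearman_r < 0 & rows$p_adj < 0.05
  rownames(rows) <- NULL
  rows
}

#' Overlap and directional concordance of two DMP sets
#'
#' @param a,b `DmpResult` data frames.
#' @param labels Length-2 character labels.
#' @return `OverlapResult` list: per-side sizes, intersection size, and the
#'   count/fraction of intersecting probes sharing direction.
#' @export
overlap_dmps <- function(a, b, labels = c("a", "b")) {
  da <- a[a$is_dmp, c("probe_id", "direction")]
  db <- b[b$is_dmp, c("probe_id", "direction")]
  common <- intersect(da$probe_id, db$probe_id)
  conc <- sum(da$direction[match(common, da$probe_id)] ==
                db$direction[match(common, db$probe_id)])
  list(labels = labels, n_a = nrow(da), n_b = nrow(db),
       intersection = length(common), concordant = conc,
       concordance_fraction = if (length(common) > 0) conc / length(common) else NA_real_)
}

#' Venn partition counts over multiple DMP sets
#'
#' @param sets Named list of >= 2 character vectors (e.g. DMP probe ids per
#'   comparison), or of `DmpResult` data frames (their `is_dmp` probes are
#'   used).
#' @return Named integer vector: one count per nonempty membership
#'   combination (names like `"a&b"`), partitioning the union.
#' @export
multi_set_intersection <- function(sets) {
  if (length(sets) < 2) stop("need at least two sets")
  sets <- lapply(sets, function(s) {
    if (is.data.frame(s)) s$probe_id[s$is_dmp] else s
  })
  universe <- unique(unlist(sets))
  if (length(universe) == 0) return(stats::setNames(integer(0), character(0)))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (is.null(dim(member))) member <- matrix(member, nrow = 1)
  key <- apply(member, 1, function(row) {
    paste(names(sets)[row], collapse = "&")
  })
  table_out <- table(key)
  stats::setNames(as.integer(table_out), names(table_out))
}

#' Hypergeometric over-representation of gene sets
#'
#' One-sided tail probability of observing at least the overlap between the
#' hit genes and each set under hypergeometric sampling from the universe,
#' with BH adjustment across sets. A database-agnostic replacement for
#' annotation-based enrichment: the sets are supplied by the user.
#'
#' @param hits Character vector of hit genes (must be a subset of `universe`).
#' @param universe Character vector of all eligible genes.
#' @param sets Named list: set name -> gene vector.
#' @return Data frame: set, n_set (in universe), n_overlap, p_raw, p_adj.
#' @export
gene_set_overrepresentation <- function(hits, universe, sets) {
  hits <- unique(hits)
  universe <- unique(universe)
  outside <- setdiff(hits, universe)
  if (length(outside) > 0) {
    stop("hit(s) not in universe: ", paste(utils::head(outside, 3), collapse = ", "))
  }
  rows <- lapply(names(sets), function(nm) {
    set <- intersect(unique(sets[[nm]]), universe)
    k <- length(intersect(hits, set))
    p <- stats::phyper(k - 1, length(set), length(universe) - length(set),
                       length(hits), lower.tail = FALSE)
    data.frame(set = nm, n_set = length(set), n_overlap = k, p_raw = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p_raw)
  rownames(out) <- NULL
  out
}

#' Read gene sets from a GMT-style TSV
#'
#' Each line: set name, description, then member genes, tab-separated.
#'
#' @param path File path.
#' @return Named list of gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1))
  out
}
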