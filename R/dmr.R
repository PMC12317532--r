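# Region-level differential methylation: proximity (bandwidth) clustering of
# per-probe signals with signed Stouffer combination, and a weighted
# Kolmogorov-Smirnov (GSEA-style) promoter enrichment with permutation null.

#' Combine p-values by the signed Stouffer method
#'
#' Each p-value is converted to a signed one-sided z (z_i = sign_i *
#' qnorm(1 - p_i / 2)); the combined z is their sum divided by sqrt(n) and the
#' combined p is the two-sided tail of |z|.
#'
#' @param p Two-sided p-values in (0, 1\]; zeros are clipped to 1e-300 with a
#'   warning.
#' @param signs Effect signs (+1 / -1) per p-value.
#' @return List with `z` and `p`.
#' @export
stouffer_combine <- function(p, signs) {
  if (length(p) != length(signs)) stop("p and signs must have equal length")
  if (!all(signs %in% c(-1, 1))) stop("signs must be +1 or -1")
  if (any(p <= 0)) {
    warning("p-value(s) of 0 clipped to 1e-300")
    p <- pmax(p, 1e-300)
  }
  if (any(p > 1)) stop("p-values must lie in (0, 1]")
  z <- signs * stats::qnorm(p / 2, lower.tail = FALSE)
  z_comb <- sum(z) / sqrt(length(z))
  list(z = z_comb, p = 2 * stats::pnorm(-abs(z_comb)))
}

#' Call differentially methylated regions
#'
#' Seed-and-merge region calling on the same proximity scale as kernel-based
#' DMR tools: probes with raw p below `p_seed_max` on one chromosome are
#' merged while consecutive seeds lie at most `lambda_bp` apart; each cluster
#' of at least `min_cpgs` seeds becomes a candidate region, scored by signed
#' Stouffer combination of its member p-values. BH adjustment is applied over
#' all candidates, and regions are kept when adjusted p < 0.05 and
#' |mean delta beta| exceeds `meandiff_min`.
#'
#' @param dmps `DmpResult` data frame from [call_dmps()].
#' @param annot Manifest (for positions and gene symbols).
#' @param lambda_bp Maximum gap between consecutive seed probes (default 1000).
#' @param p_seed_max Raw-p threshold defining seed probes (default 0.01).
#' @param min_cpgs Minimum seeds per region (default 2).
#' @param meandiff_min Threshold on |mean member delta beta| (default 0.10;
#'   0.08 for the sensitivity variant).
#' @param p_adj_max Threshold on the BH-adjusted Stouffer p (default 0.05).
#' @param keep_all Return every candidate (with a `significant` flag) instead
#'   of only the kept regions.
#' @return `DmrResult` data frame: chrom, start, end (1-based inclusive probe
#'   span), n_cpgs, stouffer_z, p_stouffer, p_adj, meandiff, genes, probe_ids.
#' @export
call_dmrs <- function(dmps, annot, lambda_bp = 1000, p_seed_max = 0.01,
                      min_cpgs = 2, meandiff_min = 0.10, p_adj_max = 0.05,
                      keep_all = FALSE) {
  seeds <- dmps[dmps$p_raw < p_seed_max, , drop = FALSE]
  empty <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      n_cpgs = integer(0), stouffer_z = numeric(0),
                      p_stouffer = numeric(0), p_adj = numeric(0),
                      meandiff = numeric(0), genes = character(0),
                      probe_ids = character(0), stringsAsFactors = FALSE)
  if (nrow(seeds) < min_cpgs) return(empty)
  ann <- annot[seeds$probe_id, ]
  seeds$chrom <- ann$chrom
  seeds$pos <- ann$pos
  unsorted <- any(vapply(split(seeds$pos, seeds$chrom), is.unsorted,
                         logical(1)))
  if (unsorted) warning("probes were not position-sorted; sorting internally")
  ord <- order(seeds$chrom, seeds$pos)
  seeds <- seeds[ord, ]
  ann <- ann[ord, ]
  gap_break <- c(TRUE, seeds$chrom[-1] != seeds$chrom[-nrow(seeds)] |
                   diff(seeds$pos) > lambda_bp)
  cluster <- cumsum(gap_break)
  regions <- lapply(split(seq_len(nrow(seeds)), cluster), function(idx) {
    if (length(idx) < min_cpgs) return(NULL)
    member <- seeds[idx, ]
    st <- stouffer_combine(member$p_raw, sign(member$delta_beta))
    genes <- sort(unique(unlist(ann$gene_symbols[idx])))
    data.frame(chrom = member$chrom[1],
               start = min(member$pos), end = max(member$pos),
               n_cpgs = length(idx),
               stouffer_z = st$z, p_stouffer = st$p, p_adj = NA_real_,
               meandiff = mean(member$delta_beta),
               genes = paste(genes, collapse = ";"),
               probe_ids = paste(member$probe_id, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  regions <- do.call(rbind, regions[!vapply(regions, is.null, logical(1))])
  if (is.null(regions) || nrow(regions) == 0) return(empty)
  regions$p_adj <- bh_adjust(regions$p_stouffer)
  regions$significant <- regions$p_adj < p_adj_max &
    abs(regions$meandiff) > meandiff_min
  rownames(regions) <- NULL
  if (keep_all) regions else {
    out <- regions[regions$significant, , drop = FALSE]
    out$significant <- NULL
    rownames(out) <- NULL
    out
  }
}

#' Rank probes by M-value log2 fold change
#'
#' Descending by `log2fc_m`; ties broken by lexicographic probe id so the
#' ranking is deterministic under row permutation.
#'
#' @param dmps `DmpResult` data frame.
#' @return Data frame with `probe_id` and `score`, ordered.
#' @export
rank_probes <- function(dmps) {
  if (any(!is.finite(dmps$log2fc_m))) stop("log2fc_m must be finite")
  ord <- order(-dmps$log2fc_m, dmps$probe_id)
  data.frame(probe_id = dmps$probe_id[ord], score = dmps$log2fc_m[ord],
             stringsAsFactors = FALSE)
}

# Weighted KS running-sum enrichment score (weight exponent 1).
# ranked_scores: scores in ranked order; member: logical vector same length.
gsea_running_es <- function(ranked_scores, member) {
  n <- length(ranked_scores)
  n_set <- sum(member)
  w <- abs(ranked_scores)
  sum_w <- sum(w[member])
  hit <- numeric(n)
  if (sum_w > 0) {
    hit[member] <- w[member] / sum_w
  } else {
    hit[member] <- 1 / n_set # all-zero scores: unweighted steps
  }
  miss <- numeric(n)
  miss[!member] <- 1 / (n - n_set)
  running <- cumsum(hit - miss)
  i_max <- which.max(abs(running))
  list(es = running[i_max], extremum_index = i_max, running = running)
}

#' GSEA-style promoter enrichment
#'
#' Tests each promoter probe set against a ranked probe list using the
#' weighted Kolmogorov-Smirnov running sum (weight = |score|, exponent 1).
#' The enrichment score is the running-sum extremum; the leading edge is the
#' member probes at or before the extremum (at or after it for negative
#' scores). The null is built from `n_perm` random probe sets of the same
#' size (probe-label permutation), with a per-gene seed derived from `seed`
#' and the gene name so results do not depend on evaluation order. NES is the
#' ES divided by the mean |null ES| of matching sign, and the permutation p is
#' (1 + number of same-sign nulls at least as extreme) / (1 + number of
#' same-sign nulls). BH adjustment is applied across tested genes.
#'
#' @param ranked Output of [rank_probes()] (or a data frame with `probe_id`
#'   and `score`, already ordered).
#' @param sets Named list: gene -> character vector of member probe ids.
#' @param min_cpgs Minimum set size after restriction to the ranked list
#'   (default 5; 3 for the sensitivity variant).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return `PromoterSetResult` data frame: gene, n_cpgs, es, nes, p_perm,
#'   p_adj, leading_edge (semicolon-joined probe ids).
#' @export
promoter_gsea <- function(ranked, sets, min_cpgs = 5, n_perm = 1000, seed = 1) {
  scores <- ranked$score
  ids <- ranked$probe_id
  n <- length(ids)
  rows <- lapply(names(sets), function(gene) {
    members <- intersect(sets[[gene]], ids)
    if (length(members) == 0) {
      warning("promoter set '", gene, "' has no probes in the ranked list; skipped")
      return(NULL)
    }
    if (length(members) < min_cpgs) return(NULL)
    member <- ids %in% members
    obs <- gsea_running_es(scores, member)
    # leading edge relative to the extremum
    idx <- which(member)
    le <- if (obs$es >= 0) ids[idx[idx <= obs$extremum_index]]
          else ids[idx[idx >= obs$extremum_index]]
    gene_seed <- (seed + sum(utf8ToInt(gene))) %% .Machine$integer.max
    set.seed(gene_seed)
    null_es <- vapply(seq_len(n_perm), function(i) {
      perm_member <- logical(n)
      perm_member[sample.int(n, length(members))] <- TRUE
      gsea_running_es(scores, perm_member)$es
    }, numeric(1))
    same_sign <- null_es[sign(null_es) == sign(obs$es)]
    nes <- if (length(same_sign) > 0) obs$es / mean(abs(same_sign)) else NA_real_
    p_perm <- (1 + sum(abs(same_sign) >= abs(obs$es))) / (1 + length(same_sign))
    data.frame(gene = gene, n_cpgs = length(members), es = obs$es, nes = nes,
               p_perm = p_perm, p_adj = NA_real_,
               leading_edge = paste(le, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(rows) || nrow(rows) == 0) {
    return(data.frame(gene = character(0), n_cpgs = integer(0), es = numeric(0),
                      nes = numeric(0), p_perm = numeric(0), p_adj = numeric(0),
                      leading_edge = character(0), stringsAsFactors = FALSE))
  }
  rows$p_adj <- bh_adjust(rows$p_perm)
  rownames(rows) <- NULL
  rows
}

#' Read promoter sets from a two-column TSV (gene, probe_id)
#'
#' @param path TSV path with header.
#' @return Named list gene -> probe ids.
#' @export
read_promoter_sets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  split(df[[2]], df[[1]])
}

#' Export DMRs as BED plus a statistics TSV
#'
#' @param dmrs `DmrResult` data frame.
#' @param bed_path,tsv_path Output paths (either may be `NULL` to skip).
#' @export
write_dmrs <- function(dmrs, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    write_bed(dmrs$chrom, dmrs$start, dmrs$end,
              name = ifelse(nzchar(dmrs$genes), dmrs$genes, "."),
              path = bed_path, score = round(dmrs$stouffer_z, 3))
  }
  if (!is.null(tsv_path)) {
    utils::write.table(dmrs, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}
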