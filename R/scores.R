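# Per-sample epigenetic biomarker scores: LINE-1 methylation index (surrogate
# for global hypomethylation), CGI-promoter hypermethylation index, CIMP and
# MSI decision rules, tumor mutation burden, and their group comparisons.

#' LINE-1 methylation index
#'
#' Mean beta over probes flagged as mapping to evolutionarily young LINE-1
#' (L1HS/L1PA) elements; lower values indicate global hypomethylation. The
#' flag is supplied in the manifest, so the index is relative to that list.
#'
#' @param betas Probes-by-samples beta matrix (post filtering).
#' @param annot Manifest with the `line1_young` flag.
#' @return Named numeric vector, one value per sample.
#' @export
line1_index <- function(betas, annot) {
  flagged <- intersect(rownames(betas), annot$probe_id[annot$line1_young])
  if (length(flagged) == 0) stop("no LINE-1-flagged probes among kept probes")
  colMeans(betas[flagged, , drop = FALSE])
}

#' Select the CGI-promoter hypermethylation probe set
#'
#' Intersection over a family of tumor-vs-normal contrasts of the probes that
#' are (a) called hypermethylated DMPs in every contrast, (b) located in CpG
#' islands, and (c) annotated to at least one promoter-proximal gene region
#' (5'UTR / TSS200 / TSS1500 / 1stExon).
#'
#' @param dmp_list List of `DmpResult` data frames, one per contrast.
#' @param annot Manifest.
#' @return Character vector of probe ids.
#' @export
hypermeth_index_probes <- function(dmp_list, annot) {
  if (length(dmp_list) == 0) stop("need at least one contrast")
  hyper_sets <- lapply(dmp_list, function(d) {
    d$probe_id[d$is_dmp & d$direction == "hyper"]
  })
  common <- Reduce(intersect, hyper_sets)
  ann <- annot[annot$probe_id %in% common, , drop = FALSE]
  in_island <- ann$cgi_relation == "Island"
  in_promoter <- vapply(ann$gene_regions, function(r) {
    length(intersect(r, PROMOTER_REGIONS)) > 0
  }, logical(1))
  probes <- ann$probe_id[in_island & in_promoter]
  if (length(probes) == 0) {
    stop("no common CGI-promoter hypermethylated probes; review DMP thresholds")
  }
  probes
}

#' CGI-promoter hypermethylation index
#'
#' Mean beta over a selected probe set, per sample (intended for tumor
#' samples, with the set from [hypermeth_index_probes()]).
#'
#' @param betas Beta matrix.
#' @param probes Probe ids.
#' @return Named numeric vector per sample.
#' @export
hypermeth_index <- function(betas, probes) {
  if (length(probes) == 0) stop("empty probe set")
  colMeans(betas[probes, , drop = FALSE])
}

#' CIMP classification (3-of-5 panel rule)
#'
#' A sample is CIMP positive when at least three of the five panel genes are
#' hypermethylated.
#'
#' @param statuses Logical vector of exactly 5 per-gene hypermethylation
#'   statuses.
#' @return `TRUE`/`FALSE`, or `NA` when any status is missing.
#' @export
cimp_call <- function(statuses) {
  if (length(statuses) != 5) stop("CIMP rule requires exactly 5 gene statuses")
  if (anyNA(statuses)) {
    message("missing CIMP gene status; result absent")
    return(NA)
  }
  sum(statuses) >= 3
}

#' MSI classification from BAT25/BAT26
#'
#' MSI when at least one marker is unstable; MSS when both are stable.
#'
#' @param bat25,bat26 `"stable"` or `"unstable"`.
#' @return `"MSI"` or `"MSS"`, or `NA` when a marker is missing.
#' @export
msi_call <- function(bat25, bat26) {
  if (is.na(bat25) || is.na(bat26)) {
    message("missing MSI marker; result absent")
    return(NA_character_)
  }
  if (!all(c(bat25, bat26) %in% c("stable", "unstable"))) {
    stop("markers must be 'stable' or 'unstable'")
  }
  if (bat25 == "unstable" || bat26 == "unstable") "MSI" else "MSS"
}

#' Tumor mutation burden
#'
#' TMB is the significant somatic mutation count divided by the panel size in
#' megabases; a tumor is hypermutated when TMB strictly exceeds 10 mutations
#' per Mb (a count of exactly 64 on a 6.4 Mb panel is therefore not
#' hypermutated).
#'
#' @param mutation_count Nonnegative integer count(s).
#' @param panel_mb Panel size in Mb (default 6.4).
#' @return List with `tmb` and `hypermutated`.
#' @export
tmb <- function(mutation_count, panel_mb = 6.4) {
  if (panel_mb <= 0) stop("panel_mb must be positive")
  if (any(mutation_count < 0, na.rm = TRUE)) stop("mutation count must be >= 0")
  value <- mutation_count / panel_mb
  list(tmb = value, hypermutated = value > 10)
}

#' Assemble the per-sample biomarker score panel
#'
#' @param betas Beta matrix (filtered probes).
#' @param annot Manifest.
#' @param sheet Sample sheet (optional columns: `cimp_gene1..5`,
#'   `bat25`/`bat26`, `somatic_mutation_count`).
#' @param hyper_probes Optional probe set from [hypermeth_index_probes()];
#'   when supplied the hypermethylation index is computed for every sample.
#' @return `ScorePanel` data frame keyed by sample_id.
#' @export
build_score_panel <- function(betas, annot, sheet, hyper_probes = NULL) {
  panel <- data.frame(sample_id = colnames(betas), stringsAsFactors = FALSE)
  panel$group <- sheet[panel$sample_id, "group"]
  panel$line1_index <- unname(line1_index(betas, annot)[panel$sample_id])
  if (!is.null(hyper_probes)) {
    panel$hypermeth_index <- unname(hypermeth_index(betas, hyper_probes)[panel$sample_id])
  }
  cimp_cols <- paste0("cimp_gene", 1:5)
  if (all(cimp_cols %in% names(sheet))) {
    panel$cimp_positive <- vapply(panel$sample_id, function(s) {
      st <- as.logical(unlist(sheet[s, cimp_cols]))
      if (anyNA(st)) NA else sum(st) >= 3
    }, logical(1))
  }
  if (all(c("bat25", "bat26") %in% names(sheet))) {
    panel$msi_status <- vapply(panel$sample_id, function(s) {
      b25 <- sheet[s, "bat25"]; b26 <- sheet[s, "bat26"]
      if (is.na(b25) || is.na(b26)) NA_character_
      else if (b25 == "unstable" || b26 == "unstable") "MSI" else "MSS"
    }, character(1))
  }
  if ("somatic_mutation_count" %in% names(sheet)) {
    counts <- sheet[panel$sample_id, "somatic_mutation_count"]
    panel$tmb <- counts / 6.4
    panel$hypermutated <- panel$tmb > 10
  }
  rownames(panel) <- panel$sample_id
  panel
}

#' Group comparisons and correlations of biomarker scores
#'
#' For each continuous score: Kruskal-Wallis across groups and all pairwise
#' Wilcoxon rank-sum tests with BH adjustment over the pair family. Spearman
#' correlations are reported for (LINE-1 vs hypermethylation), (TMB vs
#' LINE-1), and (TMB vs hypermethylation).
#'
#' @param panel `ScorePanel` data frame from [build_score_panel()].
#' @param sheet Sample sheet (for group labels, if absent from the panel).
#' @param min_group_n Groups smaller than this are excluded with a warning
#'   (default 2).
#' @return Nested list: `$kruskal`, `$pairwise`, `$correlations`.
#' @export
score_associations <- function(panel, sheet = NULL, min_group_n = 2) {
  if (!"group" %in% names(panel)) {
    panel$group <- sheet[panel$sample_id, "group"]
  }
  scores <- intersect(c("line1_index", "hypermeth_index", "tmb"), names(panel))
  out <- list(kruskal = list(), pairwise = list(), correlations = list())
  for (sc in scores) {
    ok <- !is.na(panel[[sc]])
    tab <- table(panel$group[ok])
    small <- names(tab)[tab < min_group_n]
    if (length(small) > 0) {
      warning("excluding group(s) with < ", min_group_n, " samples: ",
              paste(small, collapse = ", "))
    }
    groups <- names(tab)[tab >= min_group_n]
    if (length(groups) < 2) next
    vals <- split(panel[[sc]][ok & panel$group %in% groups],
                  panel$group[ok & panel$group %in% groups])
    out$kruskal[[sc]] <- kruskal_wallis(vals)
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    pw <- data.frame(
      group_a = vapply(pairs, `[`, character(1), 1),
      group_b = vapply(pairs, `[`, character(1), 2),
      p_raw = vapply(pairs, function(pr) {
        wilcoxon_rank_sum(vals[[pr[1]]], vals[[pr[2]]])
      }, numeric(1)),
      stringsAsFactors = FALSE
    )
    pw$p_adj <- bh_adjust(pw$p_raw)
    out$pairwise[[sc]] <- pw
  }
  cor_pairs <- list(line1_vs_hypermeth = c("line1_index", "hypermeth_index"),
                    tmb_vs_line1 = c("tmb", "line1_index"),
                    tmb_vs_hypermeth = c("tmb", "hypermeth_index"))
  for (nm in names(cor_pairs)) {
    cp <- cor_pairs[[nm]]
    if (!all(cp %in% names(panel))) next
    ok <- stats::complete.cases(panel[, cp])
    if (sum(ok) >= 3) {
      sp <- spearman_cor(panel[[cp[1]]][ok], panel[[cp[2]]][ok])
      out$correlations[[nm]] <- c(sp, n = sum(ok))
    }
  }
  out
}
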