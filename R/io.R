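#' @keywords internal
"_PACKAGE"

CGI_LEVELS <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "OpenSea")
GENE_REGION_LEVELS <- c("TSS200", "TSS1500", "5UTR", "1stExon", "Body", "3UTR")
PROMOTER_REGIONS <- c("5UTR", "TSS200", "TSS1500", "1stExon")

#' Split a semicolon-separated manifest field into a list of character vectors
#' @noRd
split_multi <- function(x) {
  out <- strsplit(as.character(x), ";", fixed = TRUE)
  lapply(out, function(v) {
    v <- trimws(v)
    v[nzchar(v) & !is.na(v)]
  })
}

join_multi <- function(x) vapply(x, paste, character(1), collapse = ";")

#' Read a probe-annotation manifest
#'
#' Reads the per-probe metadata table that anchors every downstream analysis:
#' genomic position, relation to CpG islands, gene regions and symbols, and
#' the mask flags used for probe filtering. Multi-valued columns
#' (`gene_regions`, `gene_symbols`) are semicolon-separated in the CSV.
#'
#' Boolean mask columns (`cross_reactive`, `snp_masked`, `line1_young`,
#' `clock_probe`) default to `FALSE` when absent; `is_cpg` defaults to `TRUE`
#' (an array probe is a CpG probe unless flagged otherwise).
#'
#' @param path Path to a CSV file with at least columns `probe_id`, `chrom`,
#'   `pos`, `cgi_relation`.
#' @return A data frame with one row per probe. `gene_regions` and
#'   `gene_symbols` are list columns of character vectors. Unknown columns
#'   are preserved.
#' @export
read_manifest <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("probe_id", "chrom", "pos", "cgi_relation")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("manifest is missing required column(s): ", paste(missing, collapse = ", "))
  }
  dup <- raw$probe_id[duplicated(raw$probe_id)]
  if (length(dup) > 0) {
    stop("duplicate probe_id in manifest: ", paste(unique(dup), collapse = ", "))
  }
  pos <- suppressWarnings(as.integer(raw$pos))
  bad <- which(is.na(pos) & !is.na(raw$pos))
  if (length(bad) > 0) {
    # +1 for the header row so the message points at the file line
    stop("unparseable pos at line ", bad[1] + 1L, ": '", raw$pos[bad[1]], "'")
  }
  if (any(pos < 1, na.rm = TRUE)) stop("manifest pos must be >= 1")
  bad_cgi <- setdiff(unique(raw$cgi_relation), CGI_LEVELS)
  if (length(bad_cgi) > 0) {
    stop("unknown cgi_relation value(s): ", paste(bad_cgi, collapse = ", "))
  }
  out <- raw
  out$pos <- pos
  out$gene_regions <- if ("gene_regions" %in% names(raw)) {
    split_multi(raw$gene_regions)
  } else {
    rep(list(character(0)), nrow(raw))
  }
  out$gene_symbols <- if ("gene_symbols" %in% names(raw)) {
    split_multi(raw$gene_symbols)
  } else {
    rep(list(character(0)), nrow(raw))
  }
  for (flag in c("cross_reactive", "snp_masked", "line1_young", "clock_probe")) {
    out[[flag]] <- if (flag %in% names(raw)) as.logical(raw[[flag]]) else FALSE
  }
  out$is_cpg <- if ("is_cpg" %in% names(raw)) as.logical(raw$is_cpg) else TRUE
  rownames(out) <- out$probe_id
  out
}

#' Write a probe-annotation manifest
#'
#' @param manifest A manifest data frame as returned by [read_manifest()].
#' @param path Output CSV path.
#' @export
write_manifest <- function(manifest, path) {
  out <- manifest
  out$gene_regions <- join_multi(out$gene_regions)
  out$gene_symbols <- join_multi(out$gene_symbols)
  cols <- c("probe_id", "chrom", "pos", "cgi_relation", "gene_regions",
            "gene_symbols", "is_cpg", "cross_reactive", "snp_masked",
            "line1_young", "clock_probe")
  cols <- c(cols, setdiff(names(out), cols))
  utils::write.csv(out[, cols], path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read or write a probes-by-samples matrix (TSV)
#'
#' Matrices are stored with probes in rows, a header row of sample ids, and
#' the probe id in the first column.
#'
#' @param path File path.
#' @return A numeric matrix with probe rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_matrix_tsv
#' @param x Numeric matrix with dimnames.
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(probe_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' @param path CSV with at least columns `sample_id` and `group`.
#' @return Data frame keyed by `sample_id`.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(sheet))) {
    stop("sample sheet needs at least sample_id and group columns")
  }
  dup <- sheet$sample_id[duplicated(sheet$sample_id)]
  if (length(dup) > 0) stop("duplicate sample_id: ", paste(dup, collapse = ", "))
  if ("age_at_sampling" %in% names(sheet) &&
      any(sheet$age_at_sampling < 0, na.rm = TRUE)) {
    stop("age_at_sampling must be >= 0")
  }
  rownames(sheet) <- sheet$sample_id
  sheet
}

assert_beta <- function(beta, what = "beta") {
  if (!is.numeric(beta)) stop(what, " values must be numeric")
  rng <- range(beta, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) {
    stop(what, " values must lie in [0,1]; found range [",
         signif(rng[1], 4), ", ", signif(rng[2], 4), "]")
  }
  invisible(TRUE)
}

#' Convert between beta values and M values
#'
#' M = log2(beta / (1 - beta)) after clipping beta into `[epsilon, 1 - epsilon]`
#' so the logit stays finite; M values are the variance-stabilised scale used
#' for per-probe statistical testing while beta values remain the
#' interpretable methylation fraction.
#'
#' @param beta Numeric vector or matrix of beta values in \[0,1\].
#' @param epsilon Clip bound in (0, 0.5); default `1e-6`.
#' @return M values with the same shape as the input.
#' @examples
#' beta_to_m(0.5) # 0
#' beta_to_m(0.8) # 2
#' m_to_beta(2)   # 0.8
#' @export
beta_to_m <- function(beta, epsilon = 1e-6) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0 || epsilon >= 0.5) {
    stop("epsilon must be a single value in (0, 0.5)")
  }
  assert_beta(beta)
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  m <- log2(b / (1 - b))
  if (is.matrix(beta)) dim(m) <- dim(beta)
  dimnames(m) <- dimnames(beta)
  m
}

#' @rdname beta_to_m
#' @param m Numeric vector or matrix of finite M values.
#' @export
m_to_beta <- function(m) {
  if (any(!is.finite(m))) stop("M values must be finite")
  b <- 2^m / (1 + 2^m)
  # guard against overflow for very large m
  b[m > 1023] <- 1
  dimnames(b) <- dimnames(m)
  b
}

#' Filter array probes
#'
#' Applies the standard exclusion criteria in a fixed order, attributing each
#' removed probe to the first criterion it fails: (1) detection failure
#' (detection P >= `detection_p_max` in one or more samples), (2)
#' cross-reactive probes, (3) probes on chrX/chrY, (4) non-CpG probes,
#' (5) SNP-masked probes.
#'
#' @param betas Probes-by-samples beta matrix.
#' @param annot Manifest data frame covering all rows of `betas`.
#' @param detection_p Optional detection-P matrix with the same shape as
#'   `betas`; when `NULL` the detection criterion is skipped.
#' @param detection_p_max Detection-P threshold, default 0.01.
#' @return A list with `kept` (surviving probe ids, in manifest order) and
#'   `removed` (named integer vector of per-criterion removal counts).
#' @export
filter_probes <- function(betas, annot, detection_p = NULL, detection_p_max = 0.01) {
  probes <- rownames(betas)
  missing <- setdiff(probes, annot$probe_id)
  if (length(missing) > 0) {
    stop("probes absent from manifest: ", paste(utils::head(missing, 3), collapse = ", "))
  }
  if (!is.null(detection_p) && !identical(dim(detection_p), dim(betas))) {
    stop("detection_p must have the same shape as betas")
  }
  ann <- annot[probes, ]
  fail_det <- if (is.null(detection_p)) {
    rep(FALSE, length(probes))
  } else {
    apply(detection_p >= detection_p_max, 1, any)
  }
  crit <- list(
    detection      = fail_det,
    cross_reactive = ann$cross_reactive,
    sex_chromosome = ann$chrom %in% c("chrX", "chrY"),
    non_cpg        = !ann$is_cpg,
    snp_masked     = ann$snp_masked
  )
  assigned <- rep(NA_character_, length(probes))
  for (name in names(crit)) {
    hit <- crit[[name]] & is.na(assigned)
    assigned[hit] <- name
  }
  removed <- vapply(names(crit), function(n) sum(assigned == n, na.rm = TRUE), integer(1))
  kept <- probes[is.na(assigned)]
  # return in manifest order
  kept <- annot$probe_id[annot$probe_id %in% kept]
  if (length(kept) == 0) stop("all probes filtered")
  list(kept = kept, removed = removed)
}

#' Quantile-normalize a beta matrix across samples
#'
#' Plain across-sample quantile normalization: every column is mapped onto the
#' mean of the column order statistics so all samples share one empirical
#' distribution; within-column ranks are preserved and ties share the mean of
#' their target quantiles. This is a simplification of probe-type-stratified
#' array normalization and is intended for normal-vs-normal comparisons where
#' no global methylation shift is expected.
#'
#' @param betas Probes-by-samples beta matrix with no missing values and at
#'   least two samples.
#' @return Normalized matrix with the same dimnames.
#' @export
quantile_normalize <- function(betas) {
  if (ncol(betas) < 2) stop("quantile normalization needs >= 2 samples")
  if (anyNA(betas)) stop("missing values present; impute upstream")
  out <- limma::normalizeQuantiles(betas, ties = TRUE)
  dimnames(out) <- dimnames(betas)
  out
}

#' Select the most variable probes
#'
#' Returns the ids of the `n` probes with the largest sample variance of beta,
#' ties broken by row (manifest) order.
#'
#' @param betas Probes-by-samples beta matrix.
#' @param n Number of probes to select (default 1000).
#' @return Character vector of probe ids, ordered by decreasing variance.
#' @export
most_variable_probes <- function(betas, n = 1000) {
  if (n > nrow(betas)) stop("n exceeds the number of probes")
  v <- apply(betas, 1, stats::var)
  ord <- order(-v, seq_along(v))
  rownames(betas)[ord[seq_len(n)]]
}

#' Export probe or region coordinates as BED
#'
#' Manifest positions are 1-based (array convention); BED output is 0-based
#' half-open.
#'
#' @param chrom,start,end 1-based inclusive coordinates.
#' @param name Feature names.
#' @param path Output path.
#' @param score Optional numeric score column (default 0).
#' @export
write_bed <- function(chrom, start, end, name, path, score = 0) {
  df <- data.frame(chrom = chrom, start = start - 1L, end = end,
                   name = name, score = score)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
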