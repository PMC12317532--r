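# End-to-end orchestration: filter -> (optional) quantile normalization ->
# per-contrast DMPs -> DMRs -> promoter enrichment -> biomarker scores ->
# clock -> methylation-expression integration -> cross-comparison overlaps.
# Every stage writes its table under the run directory and contributes to a
# machine-readable summary JSON; identical config and seed give identical
# outputs.

#' Assemble a pipeline configuration
#'
#' Inputs may be given as file paths (`manifest`, `beta`, `detection_p`,
#' `sample_sheet`, `expression`, `clock`, `promoter_sets`) or as a `data`
#' list holding the in-memory objects (as returned by [generate_dataset()]).
#'
#' @param data Optional in-memory dataset list.
#' @param paths Named list of input file paths (used when `data` is `NULL`).
#' @param contrasts List of [contrast_spec()] objects, named by contrast.
#' @param quantile_normalize Apply across-sample quantile normalization before
#'   testing (intended for normal-vs-normal runs).
#' @param dmr Named list of DMR parameters (`lambda_bp`, `min_cpgs`,
#'   `meandiff_min`).
#' @param gsea Named list of promoter-enrichment parameters (`min_cpgs`,
#'   `n_perm`).
#' @param seed Integer seed for every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(data = NULL, paths = list(), contrasts = list(),
                            quantile_normalize = FALSE,
                            dmr = list(lambda_bp = 1000, min_cpgs = 2,
                                       meandiff_min = 0.10),
                            gsea = list(min_cpgs = 5, n_perm = 1000),
                            seed = 1) {
  structure(list(data = data, paths = paths, contrasts = contrasts,
                 quantile_normalize = quantile_normalize, dmr = dmr,
                 gsea = gsea, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Paths, contrast definitions, thresholds and the seed are read from a YAML
#' file with top-level keys `paths`, `contrasts` (each with `tumor_group`,
#' `normal_group`, optional `covariates`, `adj_p_max`, `delta_beta_min`),
#' `quantile_normalize`, `dmr`, `gsea`, `seed`.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read YAML configs")
  }
  y <- yaml::read_yaml(path)
  contrasts <- lapply(y$contrasts, function(cc) {
    do.call(contrast_spec, cc)
  })
  pipeline_config(paths = y$paths, contrasts = contrasts,
                  quantile_normalize = isTRUE(y$quantile_normalize),
                  dmr = utils::modifyList(list(lambda_bp = 1000, min_cpgs = 2,
                                               meandiff_min = 0.10),
                                          y$dmr %||% list()),
                  gsea = utils::modifyList(list(min_cpgs = 5, n_perm = 1000),
                                           y$gsea %||% list()),
                  seed = y$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_pipeline_inputs <- function(config) {
  if (!is.null(config$data)) return(config$data)
  p <- config$paths
  for (key in c("manifest", "beta", "sample_sheet")) {
    if (is.null(p[[key]])) stop("missing required input path: ", key)
    if (!file.exists(p[[key]])) stop("input file does not exist: ", p[[key]])
  }
  for (key in setdiff(names(p), c("manifest", "beta", "sample_sheet"))) {
    if (!is.null(p[[key]]) && !file.exists(p[[key]])) {
      stop("input file does not exist: ", p[[key]])
    }
  }
  list(
    manifest = read_manifest(p$manifest),
    beta = read_matrix_tsv(p$beta),
    detection_p = if (!is.null(p$detection_p)) read_matrix_tsv(p$detection_p),
    sheet = read_sample_sheet(p$sample_sheet),
    expression = if (!is.null(p$expression)) read_matrix_tsv(p$expression),
    clock = if (!is.null(p$clock)) read_clock_model(p$clock),
    promoter_sets = if (!is.null(p$promoter_sets)) read_promoter_sets(p$promoter_sets)
  )
}

#' Run the full analysis pipeline
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory for stage tables and the summary JSON.
#' @return The summary list (also written to `summary.json`), with
#'   per-contrast DMP/DMR/promoter counts, score-panel association results,
#'   clock statistics, integration counts, and pairwise overlap statistics.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  inputs <- load_pipeline_inputs(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(seed = config$seed)

  ## filter
  filt <- filter_probes(inputs$beta, inputs$manifest,
                        detection_p = inputs$detection_p)
  beta <- inputs$beta[filt$kept, , drop = FALSE]
  summary$filter <- list(kept = length(filt$kept),
                         removed = as.list(filt$removed))
  if (isTRUE(config$quantile_normalize)) {
    beta <- quantile_normalize(beta)
    summary$quantile_normalized <- TRUE
  }

  ## promoter sets: from input file or derived from the manifest
  promoter_sets <- inputs$promoter_sets
  if (is.null(promoter_sets)) {
    ann <- inputs$manifest[filt$kept, ]
    has_prom <- vapply(ann$gene_regions, function(r) {
      length(intersect(r, PROMOTER_REGIONS)) > 0
    }, logical(1))
    genes <- vapply(ann$gene_symbols, function(g) {
      if (length(g) > 0) g[1] else NA_character_
    }, character(1))
    ok <- has_prom & !is.na(genes)
    promoter_sets <- split(ann$probe_id[ok], genes[ok])
  }

  ## per-contrast differential methylation
  dmp_tables <- list()
  dmr_tables <- list()
  gsea_tables <- list()
  summary$contrasts <- list()
  for (nm in names(config$contrasts)) {
    cc <- config$contrasts[[nm]]
    dmps <- dmp_analysis(beta, inputs$sheet, cc, annot = inputs$manifest)
    dmp_tables[[nm]] <- dmps
    write_dmp_table(dmps, file.path(out_dir, paste0("dmp_", nm, ".tsv")))
    dmrs <- call_dmrs(dmps, inputs$manifest,
                      lambda_bp = config$dmr$lambda_bp,
                      min_cpgs = config$dmr$min_cpgs,
                      meandiff_min = config$dmr$meandiff_min)
    dmr_tables[[nm]] <- dmrs
    write_dmrs(dmrs, bed_path = file.path(out_dir, paste0("dmr_", nm, ".bed")),
               tsv_path = file.path(out_dir, paste0("dmr_", nm, ".tsv")))
    ranked <- rank_probes(dmps)
    gsea_res <- promoter_gsea(ranked, promoter_sets,
                              min_cpgs = config$gsea$min_cpgs,
                              n_perm = config$gsea$n_perm,
                              seed = config$seed)
    gsea_tables[[nm]] <- gsea_res
    utils::write.table(gsea_res, file.path(out_dir, paste0("promoters_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    strat <- stratify_dmps(dmps, inputs$manifest)
    summary$contrasts[[nm]] <- list(
      n_tested = nrow(dmps),
      n_dmp = sum(dmps$is_dmp),
      n_hyper = sum(dmps$is_dmp & dmps$direction == "hyper"),
      n_hypo = sum(dmps$is_dmp & dmps$direction == "hypo"),
      n_dmr = nrow(dmrs),
      n_promoters_significant = sum(gsea_res$p_adj < 0.05),
      cgi_counts = as.list(as.data.frame(strat$cgi))
    )
  }

  ## biomarker scores
  hyper_probes <- tryCatch(
    hypermeth_index_probes(dmp_tables, inputs$manifest),
    error = function(e) NULL
  )
  panel <- build_score_panel(beta, inputs$manifest, inputs$sheet,
                             hyper_probes = hyper_probes)
  utils::write.csv(panel, file.path(out_dir, "score_panel.csv"), row.names = FALSE)
  assoc <- tryCatch(score_associations(panel, inputs$sheet),
                    error = function(e) NULL)
  summary$scores <- list(
    n_hypermeth_probes = length(hyper_probes),
    correlations = if (!is.null(assoc)) lapply(assoc$correlations, function(x) {
      list(r = x$r, p = x$p)
    })
  )

  ## clock
  if (!is.null(inputs$clock)) {
    ages <- predict_dnam_age(beta, inputs$clock, sheet = inputs$sheet)
    utils::write.table(ages, file.path(out_dir, "dnam_age.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sp <- spearman_cor(ages$dnam_age, ages$age_at_sampling)
    summary$clock <- list(spearman_r = sp$r, spearman_p = sp$p,
                          mean_delta = mean(ages$delta))
  }

  ## integration
  if (!is.null(inputs$expression) && length(promoter_sets) > 0) {
    mean_beta <- suppressWarnings(probe_group_mean_beta(beta, promoter_sets))
    integ <- meth_expr_correlation(mean_beta, inputs$expression)
    utils::write.table(integ, file.path(out_dir, "meth_expr.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$integration <- list(
      n_tested = nrow(integ),
      n_significant_negative = sum(integ$significant_negative)
    )
  }

  ## overlaps across contrasts
  if (length(dmp_tables) >= 2) {
    nms <- names(dmp_tables)
    pairs <- utils::combn(nms, 2, simplify = FALSE)
    summary$overlaps <- lapply(pairs, function(pr) {
      ov <- overlap_dmps(dmp_tables[[pr[1]]], dmp_tables[[pr[2]]], labels = pr)
      ov
    })
    summary$venn <- as.list(multi_set_intersection(dmp_tables))
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(summary)
}
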