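#!/usr/bin/env Rscript

# Stage 2: probe filtering and differential methylation.
#
# Filters probes (detection P, cross-reactive, sex chromosomes, non-CpG,
# SNP-masked), then for each tumor group versus its normal counterpart fits
# the covariate-adjusted moderated model on M-values and calls DMPs with the
# dual rule (BH-adjusted P < 0.01 and |delta beta| above 0.10, or 0.15 for
# the high-grade and carcinoma contrasts), DMRs (bandwidth 1000 bp, signed
# Stouffer combination), and promoter enrichment on the ranked probe list.

suppressMessages(library(methfield))
dir.create("results", showWarnings = FALSE)

manifest <- read_manifest("scratch/simdata/manifest.csv")
beta <- read_matrix_tsv("scratch/simdata/beta.tsv")
detp <- read_matrix_tsv("scratch/simdata/detection_p.tsv")
sheet <- read_sample_sheet("scratch/simdata/sample_sheet.csv")

filt <- filter_probes(beta, manifest, detection_p = detp)
cat("Filtering:", nrow(beta), "->", length(filt$kept), "probes; removed:\n")
print(filt$removed)
beta <- beta[filt$kept, ]

# the 1000 most variable probes separate tumors from normals in later plots
mvp <- most_variable_probes(beta, 1000)
writeLines(mvp, "results/most_variable_probes.txt")

contrasts <- list(
  LS_AdL_vs_normal = contrast_spec("LS_AdL", "LS_normal", delta_beta_min = 0.10),
  LS_AdH_vs_normal = contrast_spec("LS_AdH", "LS_normal", delta_beta_min = 0.15),
  LS_CRC_vs_normal = contrast_spec("LS_CRC", "LS_normal", delta_beta_min = 0.15),
  FAP_ad_vs_normal = contrast_spec("FAP_adenoma", "FAP_normal", delta_beta_min = 0.10)
)

# promoter probe sets from the manifest (gene -> promoter-region probes)
ann <- manifest[filt$kept, ]
has_prom <- vapply(ann$gene_regions, function(r) {
  length(intersect(r, c("TSS200", "TSS1500", "5UTR", "1stExon"))) > 0
}, logical(1))
genes <- vapply(ann$gene_symbols, function(g) {
  if (length(g) > 0) g[1] else NA_character_
}, character(1))
promoter_sets <- split(ann$probe_id[has_prom & !is.na(genes)],
                       genes[has_prom & !is.na(genes)])

dmp_tables <- list()
for (nm in names(contrasts)) {
  dmps <- suppressWarnings(
    dmp_analysis(beta, sheet, contrasts[[nm]], annot = manifest))
  dmp_tables[[nm]] <- dmps
  write_dmp_table(dmps, file.path("results", paste0("dmp_", nm, ".tsv")))

  strat <- stratify_dmps(dmps, manifest)
  dmrs <- call_dmrs(dmps, manifest,
                    meandiff_min = contrasts[[nm]]$delta_beta_min)
  write_dmrs(dmrs, bed_path = file.path("results", paste0("dmr_", nm, ".bed")),
             tsv_path = file.path("results", paste0("dmr_", nm, ".tsv")))

  ranked <- rank_probes(dmps)
  gsea <- promoter_gsea(ranked, promoter_sets, min_cpgs = 5,
                        n_perm = 500, seed = 1)
  write.table(gsea, file.path("results", paste0("promoters_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  cat(sprintf("\n%s: %d DMPs (%d hyper / %d hypo), %d DMRs, %d promoters at FDR < 0.05\n",
              nm, sum(dmps$is_dmp),
              sum(dmps$is_dmp & dmps$direction == "hyper"),
              sum(dmps$is_dmp & dmps$direction == "hypo"),
              nrow(dmrs), sum(gsea$p_adj < 0.05)))
  cat("  hyper DMPs by CGI class: ")
  print(strat$cgi["hyper", ])
}

cat("\nWrote per-contrast DMP/DMR/promoter tables under results/\n")
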