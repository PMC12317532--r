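#!/usr/bin/env Rscript

# Stage 5: methylation-expression integration and cross-comparison overlaps.
#
# Correlates promoter-averaged beta values with gene expression over all
# samples (negative correlation with BH-adjusted P < 0.05 is called
# significant), quantifies how the planted coupling is recovered, and
# summarizes DMP-set overlap and directional concordance across the four
# contrasts, including the Venn partition and a hypergeometric
# over-representation example on the recovered genes.

suppressMessages(library(methfield))
dir.create("results", showWarnings = FALSE)

manifest <- read_manifest("scratch/simdata/manifest.csv")
beta <- read_matrix_tsv("scratch/simdata/beta.tsv")
detp <- read_matrix_tsv("scratch/simdata/detection_p.tsv")
expr <- read_matrix_tsv("scratch/simdata/expression.tsv")
truth <- jsonlite::read_json("scratch/simdata/truth.json", simplifyVector = TRUE)
beta <- beta[filter_probes(beta, manifest, detection_p = detp)$kept, ]

## methylation vs expression over promoter probe sets
ann <- manifest[rownames(beta), ]
has_prom <- vapply(ann$gene_regions, function(r) {
  length(intersect(r, c("TSS200", "TSS1500", "5UTR", "1stExon"))) > 0
}, logical(1))
genes <- vapply(ann$gene_symbols, function(g) {
  if (length(g) > 0) g[1] else NA_character_
}, character(1))
promoter_sets <- split(ann$probe_id[has_prom & !is.na(genes)],
                       genes[has_prom & !is.na(genes)])

mb <- probe_group_mean_beta(beta, promoter_sets)
integ <- meth_expr_correlation(mb, expr)
write.table(integ, "results/meth_expr.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("Methylation-expression: %d features tested, %d significant negative\n",
            nrow(integ), sum(integ$significant_negative)))
coupled <- integ[integ$feature %in% truth$coupled_genes, ]
cat(sprintf("Planted coupled genes recovered: %d / %d\n",
            sum(coupled$significant_negative), nrow(coupled)))

## overlaps across contrasts
dmps <- lapply(c(LS_AdL = "LS_AdL", LS_AdH = "LS_AdH", LS_CRC = "LS_CRC",
                 FAP_ad = "FAP_ad"), function(g) {
  read.delim(file.path("results", paste0("dmp_", g, "_vs_normal.tsv")))
})
ov <- overlap_dmps(dmps$LS_AdL, dmps$FAP_ad, labels = c("LS_AdL", "FAP_ad"))
cat(sprintf("\nLS low-grade vs FAP adenoma DMPs: intersection %d, concordance %.2f\n",
            ov$intersection, ov$concordance_fraction))
venn <- multi_set_intersection(dmps)
cat("Venn partition of DMP sets:\n")
print(venn)

## over-representation of the recovered negatively correlated genes among
## the planted coupled set
universe <- rownames(expr)
hits <- integ$feature[integ$significant_negative]
ora <- gene_set_overrepresentation(hits, universe,
                                   list(planted_coupled = truth$coupled_genes))
cat(sprintf("\nORA of significant-negative genes in the planted coupled set: p = %.3g\n",
            ora$p_raw))

jsonlite::write_json(list(overlap_LS_AdL_FAP = ov, venn = as.list(venn),
                          ora_p = ora$p_raw),
                     "results/overlaps.json", auto_unbox = TRUE, digits = NA)
cat("\nWrote results/meth_expr.tsv and results/overlaps.json\n")
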