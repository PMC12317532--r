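#!/usr/bin/env Rscript

# Stage 3: per-sample biomarker scores.
#
# LINE-1 methylation index (global hypomethylation surrogate), CGI-promoter
# hypermethylation index over probes commonly hypermethylated in all LS tumor
# contrasts, CIMP (3-of-5 panel rule), MSI (BAT25/BAT26), and tumor mutation
# burden (count / 6.4 Mb, hypermutated above 10/Mb), followed by
# Kruskal-Wallis / pairwise Wilcoxon group comparisons and the inter-score
# Spearman correlations.

suppressMessages(library(methfield))
dir.create("results", showWarnings = FALSE)

manifest <- read_manifest("scratch/simdata/manifest.csv")
beta <- read_matrix_tsv("scratch/simdata/beta.tsv")
detp <- read_matrix_tsv("scratch/simdata/detection_p.tsv")
sheet <- read_sample_sheet("scratch/simdata/sample_sheet.csv")
beta <- beta[filter_probes(beta, manifest, detection_p = detp)$kept, ]

ls_dmps <- lapply(c("LS_AdL", "LS_AdH", "LS_CRC"), function(g) {
  read.delim(file.path("results", paste0("dmp_", g, "_vs_normal.tsv")))
})
hyper_probes <- hypermeth_index_probes(ls_dmps, manifest)
cat("Common CGI-promoter hypermethylated probes across LS tumor groups:",
    length(hyper_probes), "\n")

panel <- build_score_panel(beta, manifest, sheet, hyper_probes = hyper_probes)
write.csv(panel, "results/score_panel.csv", row.names = FALSE)

cat("\nLINE-1 index by group (mean +/- sd):\n")
agg <- aggregate(line1_index ~ group, panel, function(x) {
  sprintf("%.3f +/- %.3f", mean(x), sd(x))
})
print(agg, row.names = FALSE)

assoc <- suppressWarnings(score_associations(panel, sheet))
cat("\nKruskal-Wallis across groups, LINE-1 index: p =",
    format(assoc$kruskal$line1_index$p, digits = 3), "\n")
for (nm in names(assoc$correlations)) {
  cc <- assoc$correlations[[nm]]
  cat(sprintf("Spearman %-22s R = %+.2f (p = %.2g, n = %d)\n",
              nm, cc$r, cc$p, cc$n))
}

# MSI x hypermutation contingency in the simulated tumors
tum <- panel[!is.na(panel$msi_status) & !is.na(panel$hypermutated), ]
if (nrow(tum) > 0) {
  tab <- table(tum$msi_status, tum$hypermutated)
  cat("\nMSI x hypermutation table:\n")
  print(tab)
  if (all(dim(tab) == 2)) {
    cat("Fisher exact p =", format(fisher_exact_2x2(tab), digits = 3), "\n")
  }
}

jsonlite::write_json(assoc, "results/score_associations.json",
                     auto_unbox = TRUE, digits = NA, force = TRUE)
cat("\nWrote results/score_panel.csv and results/score_associations.json\n")
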