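#!/usr/bin/env Rscript

# Stage 4: DNA methylation age.
#
# Applies the clock (linear predictor over clock-probe beta values passed
# through the age transform) to every sample, then analyzes the delta
# (DNAm age minus age at sampling) across normal groups, age strata
# (younger vs at least 50 years), and colon location.

suppressMessages(library(methfield))
dir.create("results", showWarnings = FALSE)

manifest <- read_manifest("scratch/simdata/manifest.csv")
beta <- read_matrix_tsv("scratch/simdata/beta.tsv")
sheet <- read_sample_sheet("scratch/simdata/sample_sheet.csv")
clock <- read_clock_model("scratch/simdata/clock.csv")

ages <- predict_dnam_age(beta, clock, sheet = sheet)
write.table(ages, "results/dnam_age.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

normals <- sheet$sample_id[sheet$group %in%
                             c("LS_normal", "LS_UA_normal", "FAP_normal")]
res <- suppressWarnings(
  age_delta_analysis(ages[normals, ], sheet[normals, ]))

for (g in names(res)) {
  r <- res[[g]]
  cat(sprintf("\n%s (n = %d):\n", g, r$n))
  if (!is.null(r$spearman)) {
    cat(sprintf("  DNAm age vs age at sampling: Spearman R = %.2f (p = %.2g)\n",
                r$spearman$r, r$spearman$p))
  }
  cat(sprintf("  delta, age < 50: %.1f +/- %.1f (n = %d); age >= 50: %.1f +/- %.1f (n = %d)",
              r$delta_young["mean"], r$delta_young["sd"], r$delta_young["n"],
              r$delta_old["mean"], r$delta_old["sd"], r$delta_old["n"]))
  if (!is.null(r$wilcoxon_p)) cat(sprintf("; Wilcoxon p = %.2g", r$wilcoxon_p))
  cat("\n")
}

jsonlite::write_json(res, "results/dnam_age_analysis.json",
                     auto_unbox = TRUE, digits = NA, force = TRUE)
cat("\nWrote results/dnam_age.tsv and results/dnam_age_analysis.json\n")
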