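#!/usr/bin/env Rscript

# Stage 1: generate the synthetic surveillance cohort.
#
# Emulates the structure of a two-syndrome colorectal study: eight sample
# groups (Lynch-syndrome normal/adenoma/carcinoma sets and FAP counterparts)
# at their observed sizes, 20,000 array probes, planted CGI-promoter
# hypermethylation and open-sea hypomethylation in tumors, LINE-1 loss,
# a 353-probe epigenetic clock with an age signal, negative
# methylation-expression coupling in 40 genes, and mutation counts coupled
# to promoter hypermethylation. The truth registry records every planted
# effect; later stages recover them.

suppressMessages(library(methfield))

seed <- 1
cfg <- sim_config(seed = seed)
cat("Generating synthetic cohort (seed", seed, "):",
    cfg$n_probes, "probes,", sum(cfg$groups), "samples in",
    length(cfg$groups), "groups\n")

data <- generate_dataset(cfg)
dir <- "scratch/simdata"
write_dataset(data, dir)

cat("\nGroup sizes:\n")
print(table(data$sheet$group))
cat("\nPlanted effects:",
    sum(data$truth$dmp$direction == "hyper"), "hypermethylated probes (",
    length(unique(data$truth$hyper_genes)), "promoter clusters ),",
    sum(data$truth$dmp$direction == "hypo"), "hypomethylated probes,",
    length(data$truth$line1_probes), "LINE-1 probes shifted by",
    cfg$line1_shift, "on the logit scale\n")
cat("Expression coupling planted in", length(data$truth$coupled_genes),
    "genes; clock of", length(data$clock$coefficients), "probes\n")
cat("\nWrote", dir, "\n")
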