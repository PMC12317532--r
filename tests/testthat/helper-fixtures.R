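# Shared fixtures: all built in code at test time.

# Small two-group synthetic study used across test files.
small_sim <- function(seed = 1, ...) {
  args <- list(n_probes = 2000, groups = c(normal = 15, tumor = 15),
               tumor_groups = "tumor", n_genes = 40, n_hyper_probes = 100,
               n_hypo_probes = 100, n_line1_probes = 40, n_clock_probes = 20,
               n_coupled_genes = 10, seed = seed)
  extra <- list(...)
  for (nm in names(extra)) args[[nm]] <- extra[[nm]]
  do.call(sim_config, args)
}

# Null configuration: no planted effects anywhere.
null_sim <- function(seed = 1, ...) {
  small_sim(seed = seed, n_hyper_probes = 0, n_hypo_probes = 0,
            n_coupled_genes = 0, line1_shift = 0, ...)
}

# Hand-built manifest for toy tests.
toy_manifest <- function(probe_id, chrom = "chr1",
                         pos = seq_along(probe_id) * 100L,
                         cgi_relation = "OpenSea",
                         gene_regions = NULL, gene_symbols = NULL,
                         is_cpg = TRUE, cross_reactive = FALSE,
                         snp_masked = FALSE, line1_young = FALSE,
                         clock_probe = FALSE) {
  n <- length(probe_id)
  df <- data.frame(probe_id = probe_id, chrom = rep_len(chrom, n),
                   pos = as.integer(rep_len(pos, n)),
                   cgi_relation = rep_len(cgi_relation, n),
                   is_cpg = rep_len(is_cpg, n),
                   cross_reactive = rep_len(cross_reactive, n),
                   snp_masked = rep_len(snp_masked, n),
                   line1_young = rep_len(line1_young, n),
                   clock_probe = rep_len(clock_probe, n),
                   stringsAsFactors = FALSE)
  df$gene_regions <- if (is.null(gene_regions)) {
    rep(list(character(0)), n)
  } else gene_regions
  df$gene_symbols <- if (is.null(gene_symbols)) {
    rep(list(character(0)), n)
  } else gene_symbols
  rownames(df) <- df$probe_id
  df
}

# Minimal two-group sample sheet.
toy_sheet <- function(n_tumor = 3, n_normal = 3, ages = NULL, locations = NULL) {
  n <- n_tumor + n_normal
  ids <- sprintf("S%02d", seq_len(n))
  data.frame(sample_id = ids,
             patient_id = ids,
             group = c(rep("tumor", n_tumor), rep("normal", n_normal)),
             age_at_sampling = if (is.null(ages)) seq(40, 60, length.out = n) else ages,
             location = if (is.null(locations)) rep_len(c("proximal", "distal"), n) else locations,
             stringsAsFactors = FALSE,
             row.names = ids)
}
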