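# Synthetic methylation-array study generator. Emulates the structure of a
# two-syndrome colorectal surveillance series: paired tumor/normal samples in
# eight groups, CGI-promoter hypermethylation and open-sea hypomethylation
# planted in tumors on the logit scale, LINE-1 loss in tumors, an age signal
# in clock probes, negative methylation-to-expression coupling, and mutation
# counts coupled to promoter hypermethylation. Every planted effect is
# recorded in a truth registry for parameter-recovery tests.
#
# Randomness is organized as ordered substreams: each generation stage seeds
# its own stream from the global seed plus a fixed offset, so adding a later
# feature never perturbs earlier draws.

#' Simulation configuration
#'
#' Defaults reproduce the structure of the emulated study: the eight sample
#' groups at their observed sizes, planted effect size delta beta = 0.2 (the
#' middle of the reported per-probe effect range), within-group beta noise
#' with concentration 50 (sd about 0.05 near beta = 0.5), a LINE-1 logit
#' shift of -0.3 in tumors, and 40 negatively expression-coupled genes.
#' The clock predictor noise (sd 0.3 in transformed-age units) is calibrated
#' so the expected DNAm-age/age concordance matches the strongest correlation
#' the emulated study reports in normal colon (Spearman R about 0.94).
#'
#' @param n_probes Total probes on the synthetic array.
#' @param groups Named integer vector of per-group sample counts.
#' @param tumor_groups Which group labels receive planted tumor effects.
#' @param pairing Named character vector: tumor group -> its normal group
#'   (used for pair_id assignment); defaults pair `LS_*` tumors to
#'   `LS_normal`, `FAP_*` tumors to `FAP_normal`, and any other tumor group
#'   to the first non-tumor group.
#' @param n_genes Number of genes, each with an Island promoter probe cluster.
#' @param cluster_size_range Min/max promoter-cluster size (probes per gene).
#' @param n_hyper_probes Probes planted hypermethylated in tumors (taken as
#'   whole promoter clusters, preferentially Island + promoter).
#' @param n_hypo_probes Probes planted hypomethylated in tumors (scattered
#'   open-sea/body probes).
#' @param delta_hyper,delta_hypo Planted |delta beta| at the baseline.
#' @param concentration Beta-distribution concentration of within-group noise.
#' @param n_line1_probes Probes flagged as young-LINE-1.
#' @param line1_shift Logit2 shift of LINE-1 probes in tumors (negative).
#' @param n_clock_probes Clock probes (>= 10; default 353, the size of the
#'   published multi-tissue clock).
#' @param clock_noise_sd SD of the noise added to the clock linear predictor
#'   (transformed-age units).
#' @param adult_age Clock transform transition age.
#' @param n_coupled_genes Genes whose expression is negatively coupled to
#'   promoter methylation (must not exceed the number of hyper-planted genes
#'   when positive).
#' @param expr_slope Expression change per unit promoter M-value (negative).
#' @param expr_noise_sd SD of expression noise.
#' @param tmb_intercept,tmb_slope,tmb_noise_sd Mutation-count model
#'   `count = round(a + b * hypermethylation_index + noise)`, b > 0, clamped
#'   at zero. The defaults place the hypermutation boundary (64 mutations =
#'   10/Mb on the 6.4 Mb panel) at mid-severity, reproducing the emulated
#'   study's hypermutated fraction (~0.6) and TMB range (0 to ~39/Mb), with
#'   low-severity tumors near zero burden.
#' @param detection_fail_rate Fraction of probes given a failing detection P
#'   in at least one sample.
#' @param severity_range Per-tumor-sample multiplier range applied to all
#'   planted effects (drives the inter-score correlations).
#' @param seed Integer seed fixing every draw.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_probes = 20000,
                       groups = c(LS_UA_normal = 16, LS_normal = 32,
                                  LS_AdL = 21, LS_AdH = 7, LS_CRC = 5,
                                  FAP_normal = 31, FAP_adenoma = 25,
                                  FAP_carcinoma = 1),
                       tumor_groups = c("LS_AdL", "LS_AdH", "LS_CRC",
                                        "FAP_adenoma", "FAP_carcinoma"),
                       pairing = NULL,
                       n_genes = 200,
                       cluster_size_range = c(3, 8),
                       n_hyper_probes = 300,
                       n_hypo_probes = 400,
                       delta_hyper = 0.2,
                       delta_hypo = 0.2,
                       concentration = 50,
                       n_line1_probes = 200,
                       line1_shift = -0.3,
                       n_clock_probes = 353,
                       clock_noise_sd = 0.3,
                       adult_age = 20,
                       n_coupled_genes = 40,
                       expr_slope = -3,
                       expr_noise_sd = 0.5,
                       tmb_intercept = -475,
                       tmb_slope = 1500,
                       tmb_noise_sd = 15,
                       detection_fail_rate = 0.005,
                       severity_range = c(0.6, 1.4),
                       seed = 1) {
  tumor_groups <- intersect(tumor_groups, names(groups))
  normal_groups <- setdiff(names(groups), tumor_groups)
  if (length(normal_groups) == 0) stop("at least one non-tumor group required")
  if (is.null(pairing)) {
    pairing <- vapply(tumor_groups, function(g) {
      if (startsWith(g, "LS_") && "LS_normal" %in% normal_groups) "LS_normal"
      else if (startsWith(g, "FAP") && "FAP_normal" %in% normal_groups) "FAP_normal"
      else normal_groups[1]
    }, character(1))
  }
  cfg <- list(n_probes = n_probes, groups = groups,
              tumor_groups = tumor_groups, normal_groups = normal_groups,
              pairing = pairing, n_genes = n_genes,
              cluster_size_range = cluster_size_range,
              n_hyper_probes = n_hyper_probes, n_hypo_probes = n_hypo_probes,
              delta_hyper = delta_hyper, delta_hypo = delta_hypo,
              concentration = concentration,
              n_line1_probes = n_line1_probes, line1_shift = line1_shift,
              n_clock_probes = n_clock_probes, clock_noise_sd = clock_noise_sd,
              adult_age = adult_age, n_coupled_genes = n_coupled_genes,
              expr_slope = expr_slope, expr_noise_sd = expr_noise_sd,
              tmb_intercept = tmb_intercept, tmb_slope = tmb_slope,
              tmb_noise_sd = tmb_noise_sd,
              detection_fail_rate = detection_fail_rate,
              severity_range = severity_range, seed = seed)
  if (delta_hyper <= 0 || delta_hyper >= 1 || delta_hypo <= 0 || delta_hypo >= 1) {
    stop("effect sizes must lie in (0,1)")
  }
  if (detection_fail_rate < 0 || detection_fail_rate > 1) {
    stop("detection_fail_rate must lie in [0,1]")
  }
  structure(cfg, class = "sim_config")
}

# Fixed substream offsets; append-only so earlier stages are never perturbed.
SIM_STAGE_SEEDS <- c(manifest = 1L, baseline = 2L, plant = 3L, sheet = 4L,
                     beta = 5L, clock = 6L, expression = 7L, detection = 8L,
                     mutation = 9L)

stage_seed <- function(config, stage) {
  (config$seed + SIM_STAGE_SEEDS[[stage]]) %% .Machine$integer.max
}

# Group-specific age distributions (mean, sd in years) matching the emulated
# study's sample characteristics; unknown labels draw uniformly from 30-75.
SIM_AGE_PARAMS <- list(
  LS_UA_normal = c(39.4, 7.2), LS_normal = c(54.6, 10.7),
  LS_AdL = c(54.4, 10.3), LS_AdH = c(55.1, 12.0), LS_CRC = c(56.2, 9.7),
  FAP_normal = c(49.8, 16.6), FAP_adenoma = c(48.5, 16.3),
  FAP_carcinoma = c(70, 5)
)

#' Build a synthetic clock model and its probe beta values
#'
#' Constructs clock-probe beta values so the clock's linear predictor equals
#' the age transform of each sample's true age plus Gaussian noise: weights
#' `w` and per-probe baselines `b0` are drawn, contributions are scaled so
#' `sum(w * u) = 1`, and `beta_j(s) = b0_j + u_j * (F(age_s) + noise_s)` with
#' the intercept set to `-sum(w * b0)`. With zero noise the predicted age
#' equals the true age exactly.
#'
#' @param probe_ids Clock probe ids (>= 10).
#' @param ages Named vector of true ages (names = sample ids).
#' @param noise_sd Predictor noise SD (transformed-age units).
#' @param adult_age Transform transition age.
#' @param seed Integer seed.
#' @return List with `clock` (a [clock_model()]) and `beta` (clock-probes by
#'   samples matrix).
#' @export
simulate_clock_model <- function(probe_ids, ages, noise_sd = 0.5,
                                 adult_age = 20, seed = 1) {
  k <- length(probe_ids)
  if (k < 10) stop("need at least 10 clock probes")
  set.seed(seed %% .Machine$integer.max)
  # small per-probe age loadings u (|u| <= 0.06 keeps beta inside (0,1) for
  # ages 0-120 without clipping); weights scaled so sum(w * u) = 1, which
  # keeps individual coefficients small and the prediction robust to
  # dropped probes
  sgn <- rep_len(c(1, -1), k)
  u <- sgn * stats::runif(k, 0.03, 0.06)
  w <- sgn * stats::runif(k, 0.5, 1.5)
  w <- w / sum(w * u)
  b0 <- stats::runif(k, 0.42, 0.58)
  intercept <- -sum(w * b0)
  t_true <- age_transform(ages, adult_age)
  t_noisy <- t_true + stats::rnorm(length(ages), 0, noise_sd)
  beta <- matrix(b0, k, length(ages)) + outer(u, t_noisy)
  beta <- pmin(pmax(beta, 1e-4), 1 - 1e-4)
  dimnames(beta) <- list(probe_ids, names(ages))
  list(clock = clock_model(intercept, stats::setNames(w, probe_ids),
                           adult_age = adult_age),
       beta = beta)
}

#' Generate a complete synthetic methylation study
#'
#' @param config A [sim_config()].
#' @return List with `manifest`, `beta`, `detection_p`, `sheet`,
#'   `expression`, `clock`, and `truth` (the planted-effect registry:
#'   per-probe differential status and direction, planted region intervals,
#'   LINE-1 probe set, coupled genes, true ages, per-sample severity, and the
#'   promoter probe sets).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config

  ## stage 1: manifest -------------------------------------------------------
  set.seed(stage_seed(cfg, "manifest"))
  cluster_sizes <- sample(seq(cfg$cluster_size_range[1], cfg$cluster_size_range[2]),
                          cfg$n_genes, replace = TRUE)
  n_body <- sample(1:2, cfg$n_genes, replace = TRUE)
  gene_names <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  n_gene_probes <- sum(cluster_sizes) + sum(n_body)
  n_special <- cfg$n_line1_probes + cfg$n_clock_probes
  n_filler <- cfg$n_probes - n_gene_probes - n_special
  if (n_filler < 0) {
    stop("inconsistent config: gene, LINE-1 and clock probes exceed n_probes")
  }

  chroms <- paste0("chr", 1:22)
  cursor <- stats::setNames(rep(1e6, 22), chroms)
  rows <- vector("list", cfg$n_genes)
  for (g in seq_len(cfg$n_genes)) {
    chr <- chroms[(g - 1) %% 22 + 1]
    k <- cluster_sizes[g]
    offsets <- cumsum(sample(30:60, k + n_body[g], replace = TRUE))
    pos <- cursor[chr] + offsets
    cursor[chr] <- max(pos) + 10000
    regions <- c(sample(PROMOTER_REGIONS, k, replace = TRUE), rep("Body", n_body[g]))
    cgi <- c(rep("Island", k),
             sample(c("N_Shore", "S_Shore", "OpenSea"), n_body[g], replace = TRUE))
    rows[[g]] <- data.frame(chrom = chr, pos = as.integer(pos),
                            cgi_relation = cgi, region = regions,
                            gene = gene_names[g], stringsAsFactors = FALSE)
  }
  gene_df <- do.call(rbind, rows)

  special_filler <- function(n, chrom_pool = chroms) {
    chr <- sample(chrom_pool, n, replace = TRUE)
    pos <- integer(n)
    for (i in seq_len(n)) {
      pos[i] <- as.integer(cursor[chr[i]])
      cursor[chr[i]] <<- cursor[chr[i]] + sample(2000:5000, 1)
    }
    data.frame(chrom = chr, pos = pos, stringsAsFactors = FALSE)
  }
  line1_df <- special_filler(cfg$n_line1_probes)
  clock_df <- special_filler(cfg$n_clock_probes)
  filler_df <- special_filler(n_filler)
  filler_df$cgi_relation <- sample(CGI_LEVELS, n_filler, replace = TRUE,
                                   prob = c(0.10, 0.08, 0.08, 0.05, 0.05, 0.64))
  # a slice of filler probes exercises each filter criterion
  n_bad <- max(0L, round(0.01 * n_filler))
  bad_cross <- seq_len(n_bad)
  bad_snp <- n_bad + seq_len(n_bad)
  bad_noncpg <- 2L * n_bad + seq_len(max(0L, round(n_bad / 2)))
  bad_sex <- utils::tail(seq_len(n_filler), n_bad)
  filler_df$chrom[bad_sex] <- sample(c("chrX", "chrY"), length(bad_sex), replace = TRUE)

  manifest <- data.frame(
    probe_id = sprintf("cg%08d", seq_len(cfg$n_probes)),
    chrom = c(gene_df$chrom, line1_df$chrom, clock_df$chrom, filler_df$chrom),
    pos = c(gene_df$pos, line1_df$pos, clock_df$pos, filler_df$pos),
    cgi_relation = c(gene_df$cgi_relation,
                     rep("OpenSea", cfg$n_line1_probes),
                     sample(c("Island", "OpenSea"), cfg$n_clock_probes, replace = TRUE),
                     filler_df$cgi_relation),
    stringsAsFactors = FALSE
  )
  n_total <- nrow(manifest)
  manifest$gene_regions <- c(lapply(gene_df$region, identity),
                             rep(list(character(0)), n_total - nrow(gene_df)))
  manifest$gene_symbols <- c(lapply(gene_df$gene, identity),
                             rep(list(character(0)), n_total - nrow(gene_df)))
  manifest$is_cpg <- TRUE
  manifest$cross_reactive <- FALSE
  manifest$snp_masked <- FALSE
  manifest$line1_young <- FALSE
  manifest$clock_probe <- FALSE
  line1_idx <- nrow(gene_df) + seq_len(cfg$n_line1_probes)
  clock_idx <- nrow(gene_df) + cfg$n_line1_probes + seq_len(cfg$n_clock_probes)
  filler_idx <- nrow(gene_df) + n_special + seq_len(n_filler)
  manifest$line1_young[line1_idx] <- TRUE
  manifest$clock_probe[clock_idx] <- TRUE
  manifest$cross_reactive[filler_idx[bad_cross]] <- TRUE
  manifest$snp_masked[filler_idx[bad_snp]] <- TRUE
  manifest$is_cpg[filler_idx[bad_noncpg]] <- FALSE
  rownames(manifest) <- manifest$probe_id
  probe_gene <- c(gene_df$gene, rep(NA_character_, n_total - nrow(gene_df)))
  promoter_sets <- split(manifest$probe_id[seq_len(nrow(gene_df))][gene_df$region != "Body"],
                         gene_df$gene[gene_df$region != "Body"])

  ## stage 2: baseline beta --------------------------------------------------
  set.seed(stage_seed(cfg, "baseline"))
  base <- numeric(n_total)
  cgi <- manifest$cgi_relation
  base[cgi == "Island"] <- stats::rbeta(sum(cgi == "Island"), 1.5, 8)
  base[cgi %in% c("N_Shore", "S_Shore")] <-
    stats::rbeta(sum(cgi %in% c("N_Shore", "S_Shore")), 2, 2)
  base[cgi %in% c("N_Shelf", "S_Shelf")] <-
    stats::rbeta(sum(cgi %in% c("N_Shelf", "S_Shelf")), 4, 2)
  base[cgi == "OpenSea"] <- stats::rbeta(sum(cgi == "OpenSea"), 8, 2.5)
  base[line1_idx] <- stats::rbeta(cfg$n_line1_probes, 73, 27)
  base[clock_idx] <- stats::runif(cfg$n_clock_probes, 0.35, 0.65)
  base <- pmin(pmax(base, 0.02), 0.98)

  ## stage 3: planted effects ------------------------------------------------
  set.seed(stage_seed(cfg, "plant"))
  hyper_idx <- integer(0)
  hyper_genes <- character(0)
  if (cfg$n_hyper_probes > 0) {
    gene_order <- sample(gene_names)
    for (g in gene_order) {
      if (length(hyper_idx) >= cfg$n_hyper_probes) break
      idx <- which(probe_gene == g & manifest$cgi_relation == "Island")
      take <- idx[seq_len(min(length(idx), cfg$n_hyper_probes - length(hyper_idx)))]
      hyper_idx <- c(hyper_idx, take)
      hyper_genes <- c(hyper_genes, g)
    }
    if (length(hyper_idx) < cfg$n_hyper_probes) {
      stop("inconsistent config: not enough Island promoter probes to plant ",
           cfg$n_hyper_probes, " hypermethylated probes")
    }
    base[hyper_idx] <- pmin(base[hyper_idx], 1 - cfg$delta_hyper - 0.05)
  }
  if (cfg$n_coupled_genes > length(hyper_genes)) {
    stop("inconsistent config: n_coupled_genes exceeds hyper-planted genes")
  }
  coupled_genes <- utils::head(hyper_genes, cfg$n_coupled_genes)

  hypo_pool <- setdiff(which(manifest$cgi_relation %in% c("OpenSea") &
                               !manifest$line1_young & !manifest$clock_probe &
                               !manifest$cross_reactive & !manifest$snp_masked &
                               manifest$is_cpg &
                               !manifest$chrom %in% c("chrX", "chrY")),
                       c(hyper_idx))
  if (cfg$n_hypo_probes > length(hypo_pool)) {
    stop("inconsistent config: not enough open-sea probes to plant ",
         cfg$n_hypo_probes, " hypomethylated probes")
  }
  hypo_idx <- sort(sample(hypo_pool, cfg$n_hypo_probes))
  if (length(hypo_idx) > 0) {
    base[hypo_idx] <- pmax(base[hypo_idx], cfg$delta_hypo + 0.05)
  }

  dm_hyper <- beta_to_m(pmin(base + cfg$delta_hyper, 1)) - beta_to_m(base)
  dm_hypo <- beta_to_m(pmax(base - cfg$delta_hypo, 0)) - beta_to_m(base)

  ## stage 4: sample sheet ---------------------------------------------------
  set.seed(stage_seed(cfg, "sheet"))
  n_samples <- sum(cfg$groups)
  group <- rep(names(cfg$groups), cfg$groups)
  sample_id <- sprintf("S%03d", seq_len(n_samples))
  age <- numeric(n_samples)
  location <- character(n_samples)
  for (g in names(cfg$groups)) {
    sel <- which(group == g)
    pars <- SIM_AGE_PARAMS[[g]]
    age[sel] <- if (!is.null(pars)) {
      pmax(18, stats::rnorm(length(sel), pars[1], pars[2]))
    } else {
      stats::runif(length(sel), 30, 75)
    }
    location[sel] <- if (startsWith(g, "FAP")) {
      "distal"
    } else {
      sample(c("proximal", "distal"), length(sel), replace = TRUE,
             prob = c(0.7, 0.3))
    }
  }
  patient_id <- sprintf("P%03d", seq_len(n_samples))
  pair_id <- rep(NA_character_, n_samples)
  is_tumor <- group %in% cfg$tumor_groups
  for (g in cfg$tumor_groups) {
    tum <- which(group == g)
    nor <- which(group == cfg$pairing[[g]])
    if (length(nor) == 0) next
    match_idx <- nor[(seq_along(tum) - 1L) %% length(nor) + 1L]
    pair_id[tum] <- sample_id[match_idx]
    patient_id[tum] <- patient_id[match_idx]
    age[tum] <- age[match_idx]
    location[tum] <- location[match_idx]
  }
  severity <- rep(NA_real_, n_samples)
  severity[is_tumor] <- stats::runif(sum(is_tumor),
                                     cfg$severity_range[1], cfg$severity_range[2])
  cimp <- matrix(NA, n_samples, 5,
                 dimnames = list(sample_id, paste0("cimp_gene", 1:5)))
  bat25 <- rep(NA_character_, n_samples)
  bat26 <- rep(NA_character_, n_samples)
  for (i in which(is_tumor)) {
    p_hyper <- min(0.9, max(0.05, 0.25 + 0.4 * (severity[i] - cfg$severity_range[1])))
    cimp[i, ] <- stats::runif(5) < p_hyper
    # marker instability tracks lesion severity steeply, emulating the
    # near-deterministic MSI / hypermutation association the study reports
    p_msi <- if (startsWith(group[i], "FAP")) 0.05 else {
      min(0.95, max(0.02, stats::plogis(8 * (severity[i] - 1))))
    }
    bat25[i] <- if (stats::runif(1) < p_msi) "unstable" else "stable"
    bat26[i] <- if (stats::runif(1) < p_msi) "unstable" else "stable"
  }
  sheet <- data.frame(sample_id = sample_id, patient_id = patient_id,
                      group = group, age_at_sampling = round(age, 1),
                      location = location, pair_id = pair_id,
                      cimp, bat25 = bat25, bat26 = bat26,
                      stringsAsFactors = FALSE)
  rownames(sheet) <- sample_id

  ## stage 5: beta matrix ----------------------------------------------------
  set.seed(stage_seed(cfg, "beta"))
  M0 <- beta_to_m(base)
  MU <- matrix(rep(M0, n_samples), nrow = n_total)
  for (i in which(is_tumor)) {
    u <- severity[i]
    if (length(hyper_idx) > 0) MU[hyper_idx, i] <- MU[hyper_idx, i] + u * dm_hyper[hyper_idx]
    if (length(hypo_idx) > 0) MU[hypo_idx, i] <- MU[hypo_idx, i] + u * dm_hypo[hypo_idx]
    if (cfg$line1_shift != 0) {
      MU[line1_idx, i] <- MU[line1_idx, i] + u * cfg$line1_shift
    }
  }
  mu_beta <- m_to_beta(MU)
  mu_beta <- pmin(pmax(mu_beta, 0.005), 0.995)
  beta <- matrix(stats::rbeta(n_total * n_samples,
                              mu_beta * cfg$concentration,
                              (1 - mu_beta) * cfg$concentration),
                 nrow = n_total,
                 dimnames = list(manifest$probe_id, sample_id))
  # guard the open interval against numerically exact 0/1
  beta <- pmin(pmax(beta, 1e-6), 1 - 1e-6)

  ## stage 6: clock ----------------------------------------------------------
  ages_named <- stats::setNames(sheet$age_at_sampling, sample_id)
  clock_sim <- simulate_clock_model(manifest$probe_id[clock_idx], ages_named,
                                    noise_sd = cfg$clock_noise_sd,
                                    adult_age = cfg$adult_age,
                                    seed = stage_seed(cfg, "clock"))
  beta[clock_idx, ] <- clock_sim$beta

  ## stage 7: expression -----------------------------------------------------
  set.seed(stage_seed(cfg, "expression"))
  expression <- matrix(8 + stats::rnorm(cfg$n_genes * n_samples, 0, 1),
                       nrow = cfg$n_genes,
                       dimnames = list(gene_names, sample_id))
  for (g in coupled_genes) {
    probes <- promoter_sets[[g]]
    mean_m <- colMeans(beta_to_m(beta[probes, , drop = FALSE]))
    expression[g, ] <- 8 + cfg$expr_slope * (mean_m - mean(mean_m)) +
      stats::rnorm(n_samples, 0, cfg$expr_noise_sd)
  }

  ## stage 8: detection P ----------------------------------------------------
  set.seed(stage_seed(cfg, "detection"))
  detection_p <- matrix(stats::runif(n_total * n_samples, 0, 0.005),
                        nrow = n_total,
                        dimnames = list(manifest$probe_id, sample_id))
  n_fail <- round(cfg$detection_fail_rate * n_filler)
  if (n_fail > 0) {
    fail_probes <- sample(setdiff(filler_idx, filler_idx[c(bad_cross, bad_snp, bad_noncpg)]),
                          n_fail)
    for (i in fail_probes) {
      cols <- sample(n_samples, sample(1:3, 1))
      detection_p[i, cols] <- stats::runif(length(cols), 0.01, 0.1)
    }
  } else {
    fail_probes <- integer(0)
  }

  ## stage 9: mutation counts ------------------------------------------------
  set.seed(stage_seed(cfg, "mutation"))
  sheet$somatic_mutation_count <- NA_integer_
  if (length(hyper_idx) > 0) {
    # targeted sequencing covers the LS arm only in the emulated study
    for (i in which(is_tumor & !startsWith(group, "FAP"))) {
      h <- mean(beta[hyper_idx, i])
      cnt <- round(cfg$tmb_intercept + cfg$tmb_slope * h +
                     stats::rnorm(1, 0, cfg$tmb_noise_sd))
      sheet$somatic_mutation_count[i] <- max(0L, as.integer(cnt))
    }
  }

  ## truth registry ----------------------------------------------------------
  dmp_truth <- data.frame(
    probe_id = manifest$probe_id[c(hyper_idx, hypo_idx)],
    direction = c(rep("hyper", length(hyper_idx)),
                  rep("hypo", length(hypo_idx))),
    stringsAsFactors = FALSE
  )
  dmr_truth <- do.call(rbind, lapply(hyper_genes, function(g) {
    idx <- intersect(hyper_idx, which(probe_gene == g))
    if (length(idx) < 2) return(NULL)
    data.frame(gene = g, chrom = manifest$chrom[idx[1]],
               start = min(manifest$pos[idx]), end = max(manifest$pos[idx]),
               n_probes = length(idx),
               probe_ids = paste(manifest$probe_id[idx], collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  truth <- list(dmp = dmp_truth, dmr_intervals = dmr_truth,
                line1_probes = manifest$probe_id[line1_idx],
                clock_probes = manifest$probe_id[clock_idx],
                hyper_genes = hyper_genes, coupled_genes = coupled_genes,
                detection_fail_probes = manifest$probe_id[fail_probes],
                ages = ages_named,
                severity = stats::setNames(severity, sample_id),
                promoter_sets = promoter_sets,
                config = cfg)

  list(manifest = manifest, beta = beta, detection_p = detection_p,
       sheet = sheet, expression = expression, clock = clock_sim$clock,
       truth = truth)
}

#' Write a synthetic dataset to disk in the package's file formats
#'
#' @param data Output of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_manifest(data$manifest, file.path(dir, "manifest.csv"))
  write_matrix_tsv(data$beta, file.path(dir, "beta.tsv"))
  write_matrix_tsv(data$detection_p, file.path(dir, "detection_p.tsv"))
  utils::write.csv(data$sheet, file.path(dir, "sample_sheet.csv"),
                   row.names = FALSE)
  write_matrix_tsv(data$expression, file.path(dir, "expression.tsv"))
  write_clock_model(data$clock, file.path(dir, "clock.csv"))
  truth <- data$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
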