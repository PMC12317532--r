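# Independent O(n^2) running-sum implementation used as the GSEA oracle.
gsea_oracle_es <- function(scores, member) {
  n <- length(scores)
  sum_w <- sum(abs(scores[member]))
  running <- numeric(n)
  for (i in seq_len(n)) {
    r <- 0
    for (j in seq_len(i)) {
      r <- if (member[j]) r + abs(scores[j]) / sum_w else r - 1 / (n - sum(member))
    }
    running[i] <- r
  }
  running[which.max(abs(running))]
}

make_dmp_table <- function(probe_id, p_raw, delta_beta, log2fc = NULL) {
  data.frame(probe_id = probe_id, p_raw = p_raw, delta_beta = delta_beta,
             log2fc_m = if (is.null(log2fc)) delta_beta * 10 else log2fc,
             direction = ifelse(delta_beta > 0, "hyper", "hypo"),
             is_dmp = TRUE, stringsAsFactors = FALSE)
}

test_that("DMR calling merges seeds within the bandwidth and splits across gaps", {
  ids <- sprintf("p%d", 1:6)
  annot <- toy_manifest(ids, pos = c(100, 140, 180, 220, 260, 300))
  annot$gene_symbols <- rep(list("GENE1"), 6)
  dmps <- make_dmp_table(ids, p_raw = rep(1e-4, 6), delta_beta = rep(0.2, 6))
  dmrs <- call_dmrs(dmps, annot)
  expect_equal(nrow(dmrs), 1)
  expect_equal(dmrs$n_cpgs, 6)
  expect_equal(dmrs$start, 100)
  expect_equal(dmrs$end, 300)
  expect_equal(dmrs$genes, "GENE1")

  # a 1500 bp gap with lambda 1000 splits the run into two regions
  annot2 <- toy_manifest(ids, pos = c(100, 200, 300, 1800, 1900, 2000))
  dmrs2 <- call_dmrs(dmps, annot2)
  expect_equal(nrow(dmrs2), 2)
  expect_equal(dmrs2$n_cpgs, c(3, 3))

  # members must lie pairwise <= lambda apart consecutively, on one chromosome
  for (k in seq_len(nrow(dmrs2))) {
    pos <- annot2[strsplit(dmrs2$probe_ids[k], ";")[[1]], "pos"]
    expect_true(all(diff(sort(pos)) <= 1000))
  }
})

test_that("DMR effect-size threshold drops and recovers borderline regions", {
  ids <- sprintf("p%d", 1:4)
  annot <- toy_manifest(ids, pos = c(100, 150, 200, 250))
  dmps <- make_dmp_table(ids, p_raw = rep(1e-5, 4), delta_beta = rep(0.09, 4))
  expect_equal(nrow(call_dmrs(dmps, annot, meandiff_min = 0.10)), 0)
  kept <- call_dmrs(dmps, annot, meandiff_min = 0.08)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$meandiff, 0.09, tolerance = 1e-12)

  # non-seed probes (large raw p) do not form regions
  weak <- make_dmp_table(ids, p_raw = rep(0.5, 4), delta_beta = rep(0.2, 4))
  expect_equal(nrow(call_dmrs(weak, annot)), 0)

  # unsorted positions are handled with a warning
  shuffled <- dmps[c(3, 1, 4, 2), ]
  expect_warning(dmrs_s <- call_dmrs(shuffled, annot, meandiff_min = 0.08),
                 "sorted")
  expect_equal(dmrs_s$n_cpgs, 4)
})

test_that("probe ranking is by descending log2 fold change with id tie-break", {
  dmps <- data.frame(probe_id = c("a", "b", "c"), log2fc_m = c(2, -1, 3),
                     stringsAsFactors = FALSE)
  expect_equal(rank_probes(dmps)$probe_id, c("c", "a", "b"))

  tied <- data.frame(probe_id = c("z", "a"), log2fc_m = c(1, 1),
                     stringsAsFactors = FALSE)
  expect_equal(rank_probes(tied)$probe_id, c("a", "z"))
  # permuting input rows leaves the output unchanged
  expect_equal(rank_probes(dmps[c(3, 1, 2), ]), rank_probes(dmps))
  expect_error(rank_probes(data.frame(probe_id = "a", log2fc_m = NA)), "finite")
})

test_that("enrichment score equals the brute-force running sum exactly", {
  set.seed(33)
  scores <- sort(rnorm(20, sd = 2), decreasing = TRUE)
  ids <- sprintf("p%02d", 1:20)
  member_ids <- sample(ids, 6)
  ranked <- data.frame(probe_id = ids, score = scores, stringsAsFactors = FALSE)

  res <- promoter_gsea(ranked, list(G = member_ids), min_cpgs = 5,
                       n_perm = 50, seed = 9)
  oracle <- gsea_oracle_es(scores, ids %in% member_ids)
  expect_equal(res$es, oracle, tolerance = 1e-12)
  expect_true(all(strsplit(res$leading_edge, ";")[[1]] %in% member_ids))
})

test_that("a set of top-ranked probes is strongly enriched and reproducible", {
  ids <- sprintf("p%02d", 1:50)
  ranked <- data.frame(probe_id = ids, score = seq(5, 0.1, length.out = 50),
                       stringsAsFactors = FALSE)
  sets <- list(TOP = ids[1:5], SMALL = ids[1:4], RANDOM = ids[c(7, 19, 23, 31, 44, 48)])
  res <- promoter_gsea(ranked, sets, min_cpgs = 5, n_perm = 1000, seed = 5)

  expect_false("SMALL" %in% res$gene) # below the minimum CpG count
  top <- res[res$gene == "TOP", ]
  expect_gt(top$es, 0.95)
  expect_lte(top$p_perm, 0.01)
  expect_equal(sort(strsplit(top$leading_edge, ";")[[1]]), sort(ids[1:5]))

  # bit-reproducible under the same seed, regardless of set evaluation order
  res2 <- promoter_gsea(ranked, sets[c(3, 1, 2)], min_cpgs = 5, n_perm = 1000, seed = 5)
  expect_equal(res[order(res$gene), c("es", "nes", "p_perm")],
               res2[order(res2$gene), c("es", "nes", "p_perm")],
               ignore_attr = TRUE)

  # doubling the permutation count moves p by less than 3 binomial SE
  res4 <- promoter_gsea(ranked, sets["RANDOM"], min_cpgs = 5, n_perm = 2000, seed = 5)
  p1 <- res[res$gene == "RANDOM", "p_perm"]
  p2 <- res4$p_perm
  se <- sqrt(p1 * (1 - p1) / 1000)
  expect_lt(abs(p1 - p2), max(3 * se, 0.01))

  # a set with no probes in the ranked list is skipped with a warning
  expect_warning(
    none <- promoter_gsea(ranked, list(GONE = c("x1", "x2", "x3", "x4", "x5")),
                          n_perm = 10, seed = 1),
    "skipped")
  expect_equal(nrow(none), 0)
})

test_that("planted promoter clusters are recovered as significant regions", {
  cfg <- small_sim(seed = 4)
  d <- generate_dataset(cfg)
  dmps <- dmp_analysis(d$beta, d$sheet, contrast_spec("tumor", "normal"),
                       annot = d$manifest)
  dmrs <- call_dmrs(dmps, d$manifest)
  planted <- d$truth$dmr_intervals
  # most planted intervals overlap a called region on the same chromosome
  hit <- vapply(seq_len(nrow(planted)), function(i) {
    any(dmrs$chrom == planted$chrom[i] &
          dmrs$start <= planted$end[i] & dmrs$end >= planted$start[i])
  }, logical(1))
  expect_gt(mean(hit), 0.8)
})
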