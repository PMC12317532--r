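test_that("LINE-1 index averages flagged probes and ignores ordering", {
  ids <- c("l1", "l2", "x1", "x2")
  annot <- toy_manifest(ids, line1_young = c(TRUE, TRUE, FALSE, FALSE))
  beta <- matrix(c(0.6, 0.8, 0.1, 0.9,
                   0.7, 0.7, 0.2, 0.3), 4, 2,
                 dimnames = list(ids, c("s1", "s2")))
  idx <- line1_index(beta, annot)
  expect_equal(unname(idx["s1"]), 0.7)
  expect_equal(unname(idx["s2"]), 0.7)

  # invariant to probe row order and sample column order
  perm <- beta[c(3, 1, 4, 2), c(2, 1)]
  expect_equal(line1_index(perm, annot)[names(idx)], idx)

  none <- toy_manifest(ids)
  expect_error(line1_index(beta, none), "LINE-1")
})

test_that("hypermethylation probe selection intersects contrasts and annotation", {
  ids <- c("a", "b", "c", "d")
  annot <- toy_manifest(ids,
                        cgi_relation = c("Island", "Island", "Island", "OpenSea"),
                        gene_regions = list("TSS200", "Body", "TSS1500", "TSS200"))
  mk <- function(hyper_ids, all_ids = ids) {
    data.frame(probe_id = all_ids,
               direction = ifelse(all_ids %in% hyper_ids, "hyper", "hypo"),
               is_dmp = all_ids %in% hyper_ids,
               stringsAsFactors = FALSE)
  }
  # probe a: hyper in all three contrasts, Island, TSS200 -> included
  # probe b: Island but Body only -> excluded; c: hyper in 2/3 -> excluded
  # probe d: promoter region but OpenSea -> excluded
  tables <- list(mk(c("a", "b", "c", "d")), mk(c("a", "b", "d")), mk(c("a", "b", "d")))
  expect_equal(hypermeth_index_probes(tables, annot), "a")

  # monotone non-increasing in the number of contrasts intersected
  one <- length(hypermeth_index_probes(tables[1], annot))
  two <- length(hypermeth_index_probes(tables[1:2], annot))
  expect_gte(one, two)

  expect_error(hypermeth_index_probes(list(mk(character(0))), annot), "thresholds")

  beta <- matrix(c(0.2, 0.4), 2, 1, dimnames = list(c("a", "c"), "s1"))
  expect_equal(unname(hypermeth_index(beta, c("a", "c"))), 0.3)
  flat <- matrix(0.5, 4, 3, dimnames = list(ids, c("s1", "s2", "s3")))
  expect_equal(unname(hypermeth_index(flat, ids)), rep(0.5, 3))
})

test_that("CIMP, MSI, and TMB rules pass exhaustive truth tables", {
  # CIMP: all 32 status vectors, positive iff >= 3 of 5 hypermethylated
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), 5))
  for (i in seq_len(nrow(grid))) {
    st <- unlist(grid[i, ])
    expect_identical(cimp_call(st), sum(st) >= 3)
  }
  expect_true(is.na(suppressMessages(cimp_call(c(TRUE, TRUE, NA, FALSE, FALSE)))))
  expect_error(cimp_call(c(TRUE, TRUE)), "exactly 5")

  # MSI: all 4 marker combinations
  expect_equal(msi_call("unstable", "stable"), "MSI")
  expect_equal(msi_call("stable", "unstable"), "MSI")
  expect_equal(msi_call("unstable", "unstable"), "MSI")
  expect_equal(msi_call("stable", "stable"), "MSS")
  expect_true(is.na(suppressMessages(msi_call(NA, "stable"))))

  # TMB: exact boundary is exclusive at 10/Mb
  at_boundary <- tmb(64)
  expect_equal(at_boundary$tmb, 10)
  expect_false(at_boundary$hypermutated)
  above <- tmb(77)
  expect_equal(above$tmb, 12.03125)
  expect_true(above$hypermutated)
  zero <- tmb(0)
  expect_equal(zero$tmb, 0)
  expect_false(zero$hypermutated)
  expect_error(tmb(-1), ">= 0")
  # linear in the count
  expect_equal(tmb(128)$tmb, 2 * tmb(64)$tmb)
})

test_that("planted tumor effects produce the expected score orderings and signs", {
  cfg <- small_sim(seed = 6)
  d <- generate_dataset(cfg)
  filt <- filter_probes(d$beta, d$manifest, d$detection_p)
  beta <- d$beta[filt$kept, ]
  dmps <- dmp_analysis(beta, d$sheet, contrast_spec("tumor", "normal"),
                       annot = d$manifest)
  hp <- hypermeth_index_probes(list(dmps), d$manifest)
  expect_gt(length(hp), 0)
  panel <- build_score_panel(beta, d$manifest, d$sheet, hyper_probes = hp)

  # tumors lose LINE-1 methylation relative to their paired normals
  tum <- d$sheet[d$sheet$group == "tumor", ]
  frac_lower <- mean(panel[tum$sample_id, "line1_index"] <
                       panel[tum$pair_id, "line1_index"])
  expect_gt(frac_lower, 0.9)

  # correlation signs: line1 vs hypermeth negative, tmb vs line1 negative,
  # tmb vs hypermeth positive (tumors only carry tmb)
  assoc <- score_associations(panel[panel$group == "tumor", ])
  expect_lt(assoc$correlations$line1_vs_hypermeth$r, 0)
  expect_lt(assoc$correlations$tmb_vs_line1$r, 0)
  expect_gt(assoc$correlations$tmb_vs_hypermeth$r, 0)
})

test_that("score associations run group tests with BH over the pair family", {
  set.seed(12)
  panel <- data.frame(
    sample_id = sprintf("S%02d", 1:15),
    group = rep(c("g1", "g2", "g3"), each = 5),
    line1_index = c(rnorm(5, 0.9, 0.005), rnorm(5, 0.7, 0.005), rnorm(5, 0.5, 0.005)),
    stringsAsFactors = FALSE
  )
  res <- score_associations(panel)
  # fully separated groups: Kruskal-Wallis H = 12.5, p < 0.01
  expect_equal(res$kruskal$line1_index$H, 12.5, tolerance = 1e-9)
  expect_lt(res$kruskal$line1_index$p, 0.01)
  expect_equal(nrow(res$pairwise$line1_index), 3)
  expect_true(all(res$pairwise$line1_index$p_adj >= res$pairwise$line1_index$p_raw))

  # two identical groups: Wilcoxon p = 1 under the tie-corrected approximation
  panel2 <- data.frame(sample_id = sprintf("S%02d", 1:10),
                       group = rep(c("a", "b"), each = 5),
                       line1_index = rep(c(0.1, 0.2, 0.3, 0.4, 0.5), 2),
                       stringsAsFactors = FALSE)
  res2 <- score_associations(panel2)
  expect_equal(res2$pairwise$line1_index$p_raw, 1)

  # undersized groups are excluded with a warning
  panel3 <- rbind(panel2, data.frame(sample_id = "S99", group = "c",
                                     line1_index = 0.9))
  expect_warning(score_associations(panel3), "excluding")
})
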