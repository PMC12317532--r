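test_that("design builder encodes group, centered age, and location", {
  sheet <- toy_sheet(3, 3)
  cc <- contrast_spec("tumor", "normal")
  dsn <- build_design(sheet, cc)
  expect_equal(dim(dsn$design), c(6, 4))
  expect_equal(unname(dsn$design[, "group"]), c(1, 1, 1, 0, 0, 0))
  expect_equal(sum(dsn$design[, "age"]), 0) # centered
  expect_equal(dsn$contrast_vec, c(0, 1, 0, 0))

  # no covariates: 6x2 design with contrast (0,1)
  dsn0 <- build_design(sheet, contrast_spec("tumor", "normal", covariates = character(0)))
  expect_equal(dim(dsn0$design), c(6, 2))
  expect_equal(dsn0$contrast_vec, c(0, 1))

  # constant location is dropped with a warning
  sheet_d <- toy_sheet(3, 3, locations = rep("distal", 6))
  expect_warning(dsn_d <- build_design(sheet_d, cc), "location")
  expect_false("location" %in% colnames(dsn_d$design))

  sheet_na <- sheet
  sheet_na$age_at_sampling[2] <- NA
  expect_error(build_design(sheet_na, cc), sheet$sample_id[2])
})

test_that("per-probe OLS matches an independent normal-equations solver", {
  sheet <- toy_sheet(3, 3)
  dsn <- build_design(sheet, contrast_spec("tumor", "normal", covariates = character(0)))
  M <- rbind(p1 = c(1, 1, 1, 0, 0, 0))
  fit <- fit_probe_models(M, dsn$design, dsn$contrast_vec)
  expect_equal(unname(fit$coef), 1)
  expect_equal(unname(fit$sigma), 0)

  set.seed(17)
  sheet2 <- toy_sheet(6, 6)
  dsn2 <- build_design(sheet2, contrast_spec("tumor", "normal"))
  M2 <- matrix(rnorm(50 * 12), 50, 12,
               dimnames = list(sprintf("p%02d", 1:50), sheet2$sample_id))
  fit2 <- fit_probe_models(M2, dsn2$design, dsn2$contrast_vec)
  X <- dsn2$design
  XtXi <- solve(t(X) %*% X)
  for (i in c(1, 17, 50)) {
    b <- XtXi %*% t(X) %*% M2[i, ]
    expect_equal(unname(fit2$coef[i]), unname(drop(b)[2]), tolerance = 1e-10)
    resid <- M2[i, ] - X %*% b
    expect_equal(unname(fit2$sigma[i]),
                 sqrt(sum(resid^2) / (12 - ncol(X))), tolerance = 1e-10)
  }
  expect_equal(fit2$df_residual, 12 - ncol(X))
  expect_error(fit_probe_models(M2[, 1:3], dsn2$design[1:3, ], dsn2$contrast_vec),
               "degrees of freedom")
})

test_that("moderated t reduces to ordinary t at d0 = 0 and cross-checks limma", {
  set.seed(42)
  M <- matrix(rnorm(200 * 12), 200, 12,
              dimnames = list(sprintf("p%03d", 1:200), sprintf("s%02d", 1:12)))
  design <- cbind(intercept = 1, group = rep(0:1, each = 6))
  fit <- fit_probe_models(M, design, c(0, 1))

  mod0 <- moderate_variances(fit, d0 = 0)
  t_ord <- fit$coef / (fit$sigma * fit$stdev_unscaled)
  expect_equal(mod0$t, t_ord, tolerance = 1e-10)

  # homoskedastic probes: infinite prior df; t matches limma exactly (the p
  # reference differs by design: normal here vs pooled-df t in limma)
  mod <- moderate_variances(fit)
  efit <- limma::eBayes(limma::lmFit(M, design))
  expect_equal(mod$d0, efit$df.prior)
  expect_equal(mod$s0sq, efit$s2.prior, tolerance = 1e-10)
  expect_equal(unname(mod$t), unname(efit$t[, 2]), tolerance = 1e-10)

  # heteroskedastic probes: finite prior df; t and p match limma
  set.seed(43)
  sd_probe <- sqrt(1 / rchisq(200, 4) * 4)
  M2 <- M * sd_probe
  fit2 <- fit_probe_models(M2, design, c(0, 1))
  mod2 <- moderate_variances(fit2)
  efit2 <- limma::eBayes(limma::lmFit(M2, design))
  expect_true(is.finite(mod2$d0))
  expect_equal(mod2$d0, efit2$df.prior, tolerance = 1e-6)
  expect_equal(mod2$s0sq, efit2$s2.prior, tolerance = 1e-6)
  expect_equal(unname(mod2$t), unname(efit2$t[, 2]), tolerance = 1e-8)
  expect_equal(unname(mod2$p_raw), unname(efit2$p.value[, 2]), tolerance = 1e-8)
})

test_that("hyperparameters recover an inverse-chi-square variance mixture", {
  set.seed(100)
  d0_true <- 4; s0sq_true <- 1; d <- 10; n <- 5000
  true_var <- s0sq_true * d0_true / rchisq(n, d0_true)
  s2 <- true_var * rchisq(n, d) / d
  fake_fit <- list(coef = rep(0, n), stdev_unscaled = rep(1, n),
                   sigma = sqrt(s2), df_residual = d,
                   probe_id = sprintf("p%04d", 1:n))
  mod <- moderate_variances(fake_fit)
  expect_gt(mod$d0, 3); expect_lt(mod$d0, 5)
  expect_gt(mod$s0sq, 0.9); expect_lt(mod$s0sq, 1.1)

  # identical variances: infinite prior df, prior variance equals that value
  same_fit <- list(coef = rep(0, 50), stdev_unscaled = rep(1, 50),
                   sigma = rep(sqrt(2.5), 50), df_residual = 8,
                   probe_id = sprintf("p%02d", 1:50))
  mod_same <- moderate_variances(same_fit)
  expect_true(is.infinite(mod_same$d0))
  expect_equal(mod_same$s0sq, 2.5, tolerance = 1e-12)

  zero_fit <- same_fit
  zero_fit$sigma <- rep(0, 50)
  expect_error(moderate_variances(zero_fit), "degenerate variance")
})

test_that("the dual DMP rule gates on adjusted p and |delta beta| together", {
  # single tested probe so BH leaves the p-value unchanged
  one_probe <- function(p_raw, beta_tumor, beta_normal, threshold) {
    mod <- list(probe_id = "p1", p_raw = p_raw, coef = 1, t = 2, df_total = 10)
    beta <- matrix(c(rep(beta_tumor, 3), rep(beta_normal, 3)), 1,
                   dimnames = list("p1", sprintf("S%02d", 1:6)))
    sheet <- toy_sheet(3, 3)
    call_dmps(mod, beta, sheet, contrast_spec("tumor", "normal",
                                              delta_beta_min = threshold))
  }
  hit <- one_probe(0.005, 0.62, 0.50, 0.10)
  expect_true(hit$is_dmp)
  expect_equal(hit$direction, "hyper")
  expect_equal(hit$delta_beta, 0.12, tolerance = 1e-12)

  # same effect fails the stricter high-grade/carcinoma threshold
  expect_false(one_probe(0.005, 0.62, 0.50, 0.15)$is_dmp)
  # large effect but non-significant p
  expect_false(one_probe(0.02, 0.80, 0.50, 0.10)$is_dmp)

  # BH monotonicity across a full analysis
  cfg <- small_sim(seed = 2)
  d <- generate_dataset(cfg)
  dmps <- dmp_analysis(d$beta, d$sheet, contrast_spec("tumor", "normal"),
                       annot = d$manifest)
  ord <- order(dmps$p_raw)
  expect_true(all(diff(dmps$p_adj[ord]) >= -1e-12))
  expect_true(all(dmps$p_adj >= dmps$p_raw - 1e-15))
  hits <- dmps[dmps$is_dmp, ]
  expect_true(all((hits$delta_beta > 0) == (hits$direction == "hyper")))
})

test_that("DMP stratification partitions by CGI class and multi-counts gene regions", {
  ids <- c("a", "b", "c", "d")
  annot <- toy_manifest(ids,
                        cgi_relation = c("Island", "Island", "OpenSea", "OpenSea"),
                        gene_regions = list("TSS200", c("TSS200", "Body"),
                                            character(0), "Body"),
                        gene_symbols = list("G1", "G2", character(0), "G3"))
  dmps <- data.frame(probe_id = ids,
                     direction = c("hyper", "hyper", "hypo", "hypo"),
                     is_dmp = c(TRUE, TRUE, TRUE, FALSE),
                     stringsAsFactors = FALSE)
  strat <- stratify_dmps(dmps, annot)
  expect_equal(strat$cgi["hyper", "Island"], 2L)
  expect_equal(strat$cgi["hypo", "OpenSea"], 1L)
  expect_equal(sum(strat$cgi), 3L) # CGI classes partition the DMP set
  # probe b contributes to both TSS200 and Body
  expect_equal(strat$gene_region["hyper", "TSS200"], 2L)
  expect_equal(strat$gene_region["hyper", "Body"], 1L)

  empty <- stratify_dmps(dmps[dmps$probe_id == "none", ], annot)
  expect_equal(sum(empty$cgi), 0L)

  bad <- dmps
  bad$probe_id[1] <- "missing_probe"
  expect_error(stratify_dmps(bad, annot), "missing_probe")
})
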