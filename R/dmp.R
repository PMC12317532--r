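# Per-probe differential methylation on M-values: ordinary least squares with
# group + covariates, empirical-Bayes variance moderation (moment matching of
# log s^2 with trigamma inversion), BH adjustment, and the dual
# significance-plus-effect-size DMP rule.

#' Specify a two-group contrast
#'
#' @param tumor_group,normal_group Group labels in the sample sheet; the
#'   contrast coefficient is tumor minus normal.
#' @param covariates Subset of `c("age", "location")` to adjust for.
#' @param adj_p_max P-value threshold (default 0.01, applied to BH-adjusted
#'   p-values unless `use_raw_p`).
#' @param delta_beta_min Effect-size threshold on |group-mean beta difference|
#'   (default 0.10; 0.15 for high-grade/carcinoma contrasts).
#' @param use_raw_p Apply the p-threshold to raw instead of adjusted p-values.
#' @return A `contrast_spec` list.
#' @export
contrast_spec <- function(tumor_group, normal_group,
                          covariates = c("age", "location"),
                          adj_p_max = 0.01, delta_beta_min = 0.10,
                          use_raw_p = FALSE) {
  stopifnot(adj_p_max > 0, delta_beta_min > 0)
  if (identical(tumor_group, normal_group)) stop("groups must be distinct")
  if (length(covariates) > 0) {
    covariates <- match.arg(covariates, several.ok = TRUE)
  }
  structure(list(tumor_group = tumor_group, normal_group = normal_group,
                 covariates = covariates, adj_p_max = adj_p_max,
                 delta_beta_min = delta_beta_min, use_raw_p = use_raw_p),
            class = "contrast_spec")
}

#' Build the design matrix for a contrast
#'
#' Columns: intercept, tumor-group indicator, centered age, and a binary
#' location indicator (when requested). A covariate that is constant across
#' the included samples is dropped with a warning to keep the design full
#' rank.
#'
#' @param sheet Sample sheet data frame.
#' @param contrast A [contrast_spec()].
#' @return List with `design` (matrix), `contrast_vec`, and `sample_ids`.
#' @export
build_design <- function(sheet, contrast) {
  keep <- sheet$group %in% c(contrast$tumor_group, contrast$normal_group)
  sub <- sheet[keep, , drop = FALSE]
  if (sum(sub$group == contrast$tumor_group) == 0 ||
      sum(sub$group == contrast$normal_group) == 0) {
    stop("both contrast groups must be present in the sample sheet")
  }
  design <- cbind(intercept = 1,
                  group = as.numeric(sub$group == contrast$tumor_group))
  if ("age" %in% contrast$covariates) {
    if (!"age_at_sampling" %in% names(sub) || anyNA(sub$age_at_sampling)) {
      bad <- if ("age_at_sampling" %in% names(sub)) {
        sub$sample_id[is.na(sub$age_at_sampling)]
      } else sub$sample_id
      stop("missing age for sample(s): ", paste(utils::head(bad, 3), collapse = ", "))
    }
    age <- sub$age_at_sampling - mean(sub$age_at_sampling)
    if (stats::var(age) == 0) {
      warning("age is constant across samples; dropping the age covariate")
    } else {
      design <- cbind(design, age = age)
    }
  }
  if ("location" %in% contrast$covariates) {
    if (!"location" %in% names(sub) || anyNA(sub$location)) {
      stop("missing location for included samples")
    }
    loc <- as.numeric(sub$location == sort(unique(sub$location))[1])
    if (length(unique(sub$location)) < 2) {
      warning("location is constant across samples; dropping the location covariate")
    } else {
      design <- cbind(design, location = loc)
    }
  }
  contrast_vec <- as.numeric(colnames(design) == "group")
  list(design = design, contrast_vec = contrast_vec, sample_ids = sub$sample_id)
}

#' Fit per-probe linear models
#'
#' Ordinary least squares of each probe's M-values on a common design matrix.
#' The residual degrees of freedom (n minus design rank) are identical across
#' probes.
#'
#' @param M Probes-by-samples M-value matrix (columns matching the design rows).
#' @param design Design matrix from [build_design()].
#' @param contrast_vec Numeric contrast vector extracting the coefficient of
#'   interest.
#' @return List with per-probe `coef`, `stdev_unscaled`
#'   (sqrt of the contrast's unscaled variance), `sigma` (residual sd), and
#'   scalar `df_residual`.
#' @export
fit_probe_models <- function(M, design, contrast_vec) {
  n <- ncol(M)
  if (nrow(design) != n) stop("design rows must match M columns")
  qr_x <- qr(design)
  df_residual <- n - qr_x$rank
  if (df_residual <= 0) stop("residual degrees of freedom <= 0")
  fit <- stats::lm.fit(design, t(M))
  coefs <- fit$coefficients
  # lm.fit returns a bare vector for a single response
  if (is.null(dim(coefs))) coefs <- matrix(coefs, ncol = 1)
  cvec <- as.numeric(contrast_vec)
  xtxi <- solve(crossprod(design))
  u <- sqrt(drop(t(cvec) %*% xtxi %*% cvec))
  res <- fit$residuals
  if (is.null(dim(res))) res <- matrix(res, ncol = 1)
  sigma2 <- colSums(res^2) / df_residual
  list(coef = drop(crossprod(coefs, cvec)),
       stdev_unscaled = rep(u, nrow(M)),
       sigma = sqrt(sigma2),
       df_residual = df_residual,
       probe_id = rownames(M))
}

# Invert the trigamma function by Newton iteration (solve trigamma(x) = y).
trigamma_inverse <- function(y, tol = 1e-8, max_iter = 50) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in seq_len(max_iter)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) / x < tol) break
  }
  x
}

#' Empirical-Bayes variance moderation
#'
#' Estimates the prior degrees of freedom d0 and prior variance s0^2 by
#' moment matching of log s^2 (digamma/trigamma inversion), squeezes each
#' probe's residual variance towards the prior, and computes moderated
#' t-statistics with d0 + d degrees of freedom. With d0 = 0 the moderated t
#' reduces exactly to the ordinary t; estimated d0 above 1e6 is reported as
#' `Inf` and the t reference becomes normal in the limit.
#'
#' Probes with zero residual variance have s^2 replaced by s0^2 before the t
#' computation and are flagged in `zero_variance`.
#'
#' @param fit Output of [fit_probe_models()].
#' @param d0 Optional fixed prior df overriding the estimate (0 gives the
#'   ordinary t).
#' @return List with `d0`, `s0sq`, `sigma_post`, `df_total`, `t`, `p_raw`,
#'   and `zero_variance`.
#' @export
moderate_variances <- function(fit, d0 = NULL) {
  s2 <- fit$sigma^2
  d <- fit$df_residual
  if (length(s2) < 10 && is.null(d0)) {
    stop("need >= 10 probes for stable hyperparameter estimation")
  }
  pos <- s2 > 0
  if (!any(pos)) stop("degenerate variance distribution: all residual sds are zero")
  if (is.null(d0)) {
    z <- log(s2[pos])
    e <- z - digamma(d / 2) + log(d / 2)
    emean <- mean(e)
    evar <- sum((e - emean)^2) / max(length(e) - 1, 1) - trigamma(d / 2)
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      if (d0 > 1e6) d0 <- Inf
      s0sq <- if (is.finite(d0)) {
        exp(emean + digamma(d0 / 2) - log(d0 / 2))
      } else {
        mean(s2[pos])
      }
    } else {
      # no excess dispersion of log s^2 beyond sampling noise: infinite prior
      # df, prior variance = mean observed variance
      d0 <- Inf
      s0sq <- mean(s2[pos])
    }
  } else {
    s0sq <- if (d0 > 0) mean(s2[pos]) else mean(s2)
  }
  s2_work <- s2
  zero_variance <- !pos
  if (d0 > 0) s2_work[zero_variance] <- s0sq
  if (is.infinite(d0)) {
    sigma_post <- rep(sqrt(s0sq), length(s2))
    df_total <- Inf
  } else if (d0 == 0) {
    sigma_post <- sqrt(s2_work)
    df_total <- d
  } else {
    sigma_post <- sqrt((d0 * s0sq + d * s2_work) / (d0 + d))
    df_total <- d0 + d
  }
  tstat <- fit$coef / (sigma_post * fit$stdev_unscaled)
  p_raw <- if (is.finite(df_total)) {
    2 * stats::pt(-abs(tstat), df = df_total)
  } else {
    2 * stats::pnorm(-abs(tstat))
  }
  list(d0 = d0, s0sq = s0sq, sigma_post = sigma_post, df_total = df_total,
       t = tstat, p_raw = p_raw, zero_variance = zero_variance,
       coef = fit$coef, probe_id = fit$probe_id)
}

#' Call differentially methylated probes
#'
#' Applies BH adjustment over all tested probes and the dual rule: a probe is
#' a DMP when its (adjusted, or raw if `use_raw_p`) p-value is below
#' `adj_p_max` AND |delta beta| exceeds `delta_beta_min`. Delta beta is the
#' covariate-unadjusted difference of group-mean beta (tumor minus normal).
#'
#' @param mod Output of [moderate_variances()].
#' @param betas Beta matrix covering the contrast samples.
#' @param sheet Sample sheet.
#' @param contrast A [contrast_spec()].
#' @param annot Optional manifest to attach chrom/pos.
#' @return A `DmpResult` data frame with columns probe_id, (chrom, pos,)
#'   log2fc_m, delta_beta, t, df_total, p_raw, p_adj, direction, is_dmp.
#' @export
call_dmps <- function(mod, betas, sheet, contrast, annot = NULL) {
  probes <- mod$probe_id
  if (!identical(probes, rownames(betas))) {
    betas <- betas[probes, , drop = FALSE]
  }
  tum <- sheet$sample_id[sheet$group == contrast$tumor_group]
  nor <- sheet$sample_id[sheet$group == contrast$normal_group]
  delta_beta <- rowMeans(betas[, tum, drop = FALSE]) -
    rowMeans(betas[, nor, drop = FALSE])
  p_adj <- bh_adjust(mod$p_raw)
  p_crit <- if (isTRUE(contrast$use_raw_p)) mod$p_raw else p_adj
  is_dmp <- (p_crit < contrast$adj_p_max) &
    (abs(delta_beta) > contrast$delta_beta_min)
  out <- data.frame(
    probe_id = probes,
    log2fc_m = unname(mod$coef),
    delta_beta = unname(delta_beta),
    t = unname(mod$t),
    df_total = mod$df_total,
    p_raw = unname(mod$p_raw),
    p_adj = unname(p_adj),
    direction = ifelse(delta_beta > 0, "hyper", "hypo"),
    is_dmp = unname(is_dmp),
    stringsAsFactors = FALSE
  )
  if (!is.null(annot)) {
    out$chrom <- annot[out$probe_id, "chrom"]
    out$pos <- annot[out$probe_id, "pos"]
    out <- out[, c("probe_id", "chrom", "pos", "log2fc_m", "delta_beta",
                   "t", "df_total", "p_raw", "p_adj", "direction", "is_dmp")]
  }
  rownames(out) <- out$probe_id
  out
}

#' Full per-contrast DMP analysis
#'
#' Convenience wrapper: design, per-probe fits, moderation, and DMP calling.
#'
#' @inheritParams call_dmps
#' @param betas Probes-by-samples beta matrix (all probes to test).
#' @param epsilon Clip bound for the beta-to-M transform.
#' @return A `DmpResult` data frame (see [call_dmps()]).
#' @export
dmp_analysis <- function(betas, sheet, contrast, annot = NULL, epsilon = 1e-6) {
  dsn <- build_design(sheet, contrast)
  sub_beta <- betas[, dsn$sample_ids, drop = FALSE]
  M <- beta_to_m(sub_beta, epsilon = epsilon)
  fit <- fit_probe_models(M, dsn$design, dsn$contrast_vec)
  mod <- moderate_variances(fit)
  call_dmps(mod, sub_beta, sheet[dsn$sample_ids, ], contrast, annot = annot)
}

#' Stratify DMP counts by annotation
#'
#' Counts called DMPs by direction within CGI-relation classes (a partition)
#' and within gene regions (a probe annotated with k regions contributes once
#' to each, so region counts can exceed the DMP count).
#'
#' @param dmps `DmpResult` data frame.
#' @param annot Manifest covering all DMP probes.
#' @return List of two direction-by-class count matrices: `cgi` and
#'   `gene_region`.
#' @export
stratify_dmps <- function(dmps, annot) {
  hits <- dmps[dmps$is_dmp, , drop = FALSE]
  unknown <- setdiff(hits$probe_id, annot$probe_id)
  if (length(unknown) > 0) {
    stop("DMP probe(s) absent from manifest: ", paste(utils::head(unknown, 3), collapse = ", "))
  }
  dirs <- c("hyper", "hypo")
  cgi <- matrix(0L, 2, length(CGI_LEVELS), dimnames = list(dirs, CGI_LEVELS))
  reg <- matrix(0L, 2, length(GENE_REGION_LEVELS),
                dimnames = list(dirs, GENE_REGION_LEVELS))
  if (nrow(hits) > 0) {
    ann <- annot[hits$probe_id, ]
    for (i in seq_len(nrow(hits))) {
      d <- hits$direction[i]
      cgi[d, ann$cgi_relation[i]] <- cgi[d, ann$cgi_relation[i]] + 1L
      for (r in intersect(ann$gene_regions[[i]], GENE_REGION_LEVELS)) {
        reg[d, r] <- reg[d, r] + 1L
      }
    }
  }
  list(cgi = cgi, gene_region = reg)
}

#' Write a DMP table as TSV
#'
#' @param dmps `DmpResult` data frame (with chrom/pos columns).
#' @param path Output path.
#' @export
write_dmp_table <- function(dmps, path) {
  utils::write.table(dmps, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
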