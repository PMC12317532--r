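# Epigenetic-clock age prediction: a penalized-regression clock is applied as
# a linear predictor over clock-probe beta values, passed through the
# nonlinear age transform used by the original multi-tissue clock.

#' The epigenetic-clock age transform and its inverse
#'
#' F(age) = log((age + 1) / (adult_age + 1)) for age <= adult_age, and
#' (age - adult_age) / (adult_age + 1) above it: logarithmic in childhood,
#' linear in adulthood, continuous and strictly increasing with
#' F(adult_age) = 0.
#'
#' @param age Age in years (> -1).
#' @param adult_age Transition age in years (default 20).
#' @return Transformed value(s).
#' @examples
#' age_transform(20) # 0
#' age_transform(41) # 1
#' age_anti_transform(1) # 41
#' @export
age_transform <- function(age, adult_age = 20) {
  if (adult_age <= 0) stop("adult_age must be positive")
  if (any(age <= -1)) stop("age must exceed -1 (transform domain)")
  ifelse(age <= adult_age,
         log((age + 1) / (adult_age + 1)),
         (age - adult_age) / (adult_age + 1))
}

#' @rdname age_transform
#' @param x Transformed value(s) (finite).
#' @export
age_anti_transform <- function(x, adult_age = 20) {
  if (any(!is.finite(x))) stop("x must be finite")
  ifelse(x < 0,
         (1 + adult_age) * exp(x) - 1,
         (1 + adult_age) * x + adult_age)
}

#' Construct a clock model
#'
#' @param intercept Real intercept of the linear predictor.
#' @param coefficients Named numeric vector: probe_id -> weight (>= 1 entry).
#' @param adult_age Transition age of the transform (default 20).
#' @return A `clock_model` list.
#' @export
clock_model <- function(intercept, coefficients, adult_age = 20) {
  if (length(coefficients) < 1) stop("clock needs at least one coefficient")
  if (is.null(names(coefficients)) || any(!nzchar(names(coefficients)))) {
    stop("coefficients must be named by probe_id")
  }
  structure(list(intercept = intercept, coefficients = coefficients,
                 adult_age = adult_age), class = "clock_model")
}

#' Read / write a clock-coefficient CSV
#'
#' The CSV has columns `probe_id` and `coefficient`, with the intercept in an
#' `(Intercept)` row. Published clock coefficients can be supplied in this
#' format; none are bundled.
#'
#' @param path CSV path.
#' @param adult_age Transition age (default 20; not stored in the CSV).
#' @return A [clock_model()].
#' @export
read_clock_model <- function(path, adult_age = 20) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "coefficient") %in% names(df))) {
    stop("clock CSV needs columns probe_id and coefficient")
  }
  is_int <- df$probe_id == "(Intercept)"
  if (sum(is_int) != 1) stop("clock CSV must contain exactly one (Intercept) row")
  coefs <- df$coefficient[!is_int]
  names(coefs) <- df$probe_id[!is_int]
  clock_model(df$coefficient[is_int], coefs, adult_age = adult_age)
}

#' @rdname read_clock_model
#' @param clock A [clock_model()].
#' @export
write_clock_model <- function(clock, path) {
  df <- data.frame(probe_id = c("(Intercept)", names(clock$coefficients)),
                   coefficient = c(clock$intercept, unname(clock$coefficients)),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Predict DNA methylation age
#'
#' Linear predictor = intercept + sum(weight * beta) over the clock probes,
#' back-transformed through [age_anti_transform()]. Missing clock probes are
#' handled per `missing_policy`: `"strict"` errors, `"warn"` drops the
#' missing terms with a warning (the common clock-tool behavior), `"impute"`
#' substitutes beta = 0.5.
#'
#' @param betas Beta matrix.
#' @param clock A [clock_model()].
#' @param missing_policy One of `"warn"`, `"strict"`, `"impute"`.
#' @param sheet Optional sample sheet with `age_at_sampling`; when given, the
#'   result includes the chronological age and `delta` = DNAm age minus age at
#'   sampling.
#' @return `AgeResult` data frame: sample_id, dnam_age, n_missing_probes, and
#'   (with a sheet) age_at_sampling and delta.
#' @export
predict_dnam_age <- function(betas, clock,
                             missing_policy = c("warn", "strict", "impute"),
                             sheet = NULL) {
  missing_policy <- match.arg(missing_policy)
  probes <- names(clock$coefficients)
  present <- probes %in% rownames(betas)
  n_missing <- sum(!present)
  if (n_missing > 0) {
    if (missing_policy == "strict") {
      stop("missing clock probe(s): ",
           paste(utils::head(probes[!present], 5), collapse = ", "))
    }
    if (missing_policy == "warn") {
      if (mean(present) < 0.5) {
        stop("fewer than 50% of clock probes present (", sum(present), "/",
             length(probes), ")")
      }
      warning(n_missing, " clock probe(s) missing; dropping their terms")
    }
  }
  if (missing_policy == "impute" && n_missing > 0) {
    b <- matrix(0.5, length(probes), ncol(betas),
                dimnames = list(probes, colnames(betas)))
    b[probes[present], ] <- betas[probes[present], , drop = FALSE]
    w <- clock$coefficients
  } else {
    b <- betas[probes[present], , drop = FALSE]
    w <- clock$coefficients[present]
  }
  predictor <- clock$intercept + drop(crossprod(b, unname(w)))
  out <- data.frame(sample_id = colnames(betas),
                    dnam_age = age_anti_transform(predictor, clock$adult_age),
                    n_missing_probes = n_missing,
                    stringsAsFactors = FALSE)
  if (!is.null(sheet)) {
    out$age_at_sampling <- sheet[out$sample_id, "age_at_sampling"]
    out$delta <- out$dnam_age - out$age_at_sampling
  }
  rownames(out) <- out$sample_id
  out
}

#' Analyze DNAm-age deltas across groups, age strata, and colon location
#'
#' Per group: Spearman correlation of DNAm age vs chronological age (omitted
#' with a warning for groups of fewer than 3 samples), mean and sd of the
#' delta (DNAm age minus age at sampling) in samples younger vs at least
#' `split_age` years with a two-sided Wilcoxon test between the strata, and
#' the same statistics stratified by location when available.
#'
#' @param ages `AgeResult` data frame (with `age_at_sampling` and `delta`).
#' @param sheet Sample sheet (for group and location).
#' @param split_age Age stratum boundary in years (default 50).
#' @return Nested list keyed by group.
#' @export
age_delta_analysis <- function(ages, sheet, split_age = 50) {
  if (!all(c("age_at_sampling", "delta") %in% names(ages))) {
    stop("ages must carry age_at_sampling and delta (predict with a sample sheet)")
  }
  ages$group <- sheet[ages$sample_id, "group"]
  ages$location <- if ("location" %in% names(sheet)) {
    sheet[ages$sample_id, "location"]
  } else NA_character_

  summarize <- function(sub) {
    res <- list(n = nrow(sub))
    if (nrow(sub) >= 3 &&
        stats::var(rank(sub$age_at_sampling)) > 0 &&
        stats::var(rank(sub$dnam_age)) > 0) {
      res$spearman <- spearman_cor(sub$dnam_age, sub$age_at_sampling)
    }
    young <- sub$delta[sub$age_at_sampling < split_age]
    old <- sub$delta[sub$age_at_sampling >= split_age]
    res$delta_young <- c(mean = mean(young), sd = stats::sd(young), n = length(young))
    res$delta_old <- c(mean = mean(old), sd = stats::sd(old), n = length(old))
    if (length(young) > 0 && length(old) > 0) {
      res$wilcoxon_p <- wilcoxon_rank_sum(young, old)
    }
    res
  }

  out <- list()
  for (g in unique(ages$group)) {
    sub <- ages[ages$group == g, , drop = FALSE]
    if (nrow(sub) < 3) {
      warning("group '", g, "' has < 3 samples; correlation omitted")
    }
    entry <- summarize(sub)
    if (!all(is.na(sub$location))) {
      entry$by_location <- lapply(split(sub, sub$location), summarize)
    }
    out[[g]] <- entry
  }
  out
}
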