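#' Logistic case-control association
#'
#' Maximum-likelihood logistic regression of case status on allele dosage
#' (plus optional covariates), with Wald two-sided p-values. Quasi-complete
#' separation (diverging estimates) is detected and raised as an error.
#'
#' @param dosage allele dosage vector (0/1/2).
#' @param status binary outcome (1 = case).
#' @param covariates optional numeric matrix of covariates.
#' @return list with `beta` (log OR per allele), `se`, `p`, `n`, plus the
#'   case/control counts `n_cases`, `n_controls`.
#' @export
logistic_assoc <- function(dosage, status, covariates = NULL) {
  ok <- !is.na(dosage) & !is.na(status)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    ok <- ok & stats::complete.cases(covariates)
  }
  dosage <- dosage[ok]; status <- status[ok]
  if (length(unique(status)) < 2L)
    stop("both outcome classes must be present", call. = FALSE)
  df <- data.frame(status = status, dosage = dosage)
  form <- status ~ dosage
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates[ok, , drop = FALSE])
    names(cv) <- paste0("cov", seq_along(cv))
    df <- cbind(df, cv)
    form <- stats::reformulate(c("dosage", names(cv)), response = "status")
  }
  fit <- stats::glm(form, family = stats::binomial(), data = df)
  cf <- summary(fit)$coefficients
  beta <- cf["dosage", "Estimate"]
  if (!fit$converged || abs(beta) > 10)
    stop("separation suspected: logistic estimate diverges (|beta| = ",
         sprintf("%.2f", abs(beta)), ")", call. = FALSE)
  list(beta = beta, se = cf["dosage", "Std. Error"],
       p = cf["dosage", "Pr(>|z|)"], n = length(status),
       n_cases = sum(status == 1), n_controls = sum(status == 0))
}

#' Fixed-effects inverse-variance meta-analysis
#'
#' Pools per-cohort log odds-ratio estimates with weights `w_i = 1/se_i^2`:
#' `beta_meta = sum(w b) / sum(w)`, `se_meta = 1/sqrt(sum(w))`, a two-sided
#' normal p-value, and Cochran's Q heterogeneity statistic with its
#' chi-squared p-value on `k - 1` degrees of freedom.
#'
#' @param beta per-study effects (log OR), or a data.frame with columns
#'   `beta` and `se` (extra columns ignored).
#' @param se per-study standard errors (when `beta` is a vector).
#' @return object of class `meta_result`: `beta`, `se`, `or`, `ci_lo`,
#'   `ci_hi` (95% CI on the OR scale), `p`, `Q`, `p_het`, `k`.
#' @export
ivw_meta <- function(beta, se = NULL) {
  if (is.data.frame(beta)) {
    se <- beta$se; beta <- beta$beta
  }
  k <- length(beta)
  if (k < 1L) stop("need at least one study", call. = FALSE)
  if (length(se) != k || any(!is.finite(se)) || any(se <= 0))
    stop("`se` must be finite and positive for every study", call. = FALSE)
  w <- 1 / se^2
  bm <- sum(w * beta) / sum(w)
  sm <- 1 / sqrt(sum(w))
  Q <- sum(w * (beta - bm)^2)
  p_het <- if (k > 1L) stats::pchisq(Q, df = k - 1L, lower.tail = FALSE) else 1
  structure(list(beta = bm, se = sm, or = exp(bm),
                 ci_lo = exp(bm - 1.96 * sm), ci_hi = exp(bm + 1.96 * sm),
                 p = 2 * stats::pnorm(-abs(bm / sm)),
                 Q = Q, p_het = p_het, k = k),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Fixed-effects inverse-variance meta-analysis (k = %d)\n", x$k))
  cat(sprintf("  OR = %.3f (95%% CI %.3f-%.3f), P = %.3g\n",
              x$or, x$ci_lo, x$ci_hi, x$p))
  cat(sprintf("  heterogeneity: Q = %.3f, P_het = %.3g\n", x$Q, x$p_het))
  invisible(x)
}

#' @export
summary.meta_result <- function(object, ...) {
  print(object)
  cat(sprintf("  log OR = %.4f (SE %.4f)\n", object$beta, object$se))
  invisible(object)
}

#' @export
coef.meta_result <- function(object, ...) c(beta = object$beta, se = object$se)

#' Class-based weighted Bonferroni significance thresholds
#'
#' Splits the tested variants into annotation classes and assigns each class
#' the threshold `alpha * w_c / sum(n_c * w_c)`, so that more numerous
#' (typically lower-impact) classes get stricter thresholds and the weighted
#' Bonferroni identity `sum(n_c * threshold_c) = alpha` holds exactly.
#'
#' @param counts named vector of variant counts per class (>= 1).
#' @param weights per-class relative weights (> 0), same length.
#' @param alpha family-wise error target.
#' @return data.frame of class `threshold_scheme`: `class`, `n`, `weight`,
#'   `threshold`.
#' @export
class_thresholds <- function(counts, weights, alpha = 0.05) {
  if (!length(counts) || any(counts < 1))
    stop("every class needs a positive variant count", call. = FALSE)
  if (length(weights) != length(counts) || any(weights <= 0))
    stop("`weights` must be positive and match `counts`", call. = FALSE)
  thr <- alpha * weights / sum(counts * weights)
  out <- data.frame(class = if (is.null(names(counts)))
    paste0("class", seq_along(counts)) else names(counts),
    n = as.numeric(counts), weight = weights, threshold = thr)
  class(out) <- c("threshold_scheme", "data.frame")
  out
}

#' Binomial enrichment test
#'
#' Exact binomial test of whether `k_hits` successes in `n_tests` trials
#' exceed (or differ from) the expectation under a per-test success
#' probability `p0`. The default is the one-sided upper tail
#' `P(X >= k_hits)`.
#'
#' @param k_hits observed number of hits.
#' @param n_tests number of tests.
#' @param p0 null per-test hit probability.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @return the p-value.
#' @export
binomial_enrichment <- function(k_hits, n_tests, p0 = 0.05,
                                alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (k_hits < 0 || k_hits > n_tests) stop("need 0 <= k_hits <= n_tests",
                                           call. = FALSE)
  stopifnot_scalar(p0, "p0", lo = .Machine$double.xmin, hi = 1 - 1e-12)
  stats::binom.test(k_hits, n_tests, p0, alternative = alternative)$p.value
}

#' Harmonize per-cohort summary statistics
#'
#' Matches variants across cohorts on (`chrom`, `pos`, `ref`, `alt`); rows
#' whose alleles appear swapped relative to the first cohort are flipped
#' (beta sign reversed, allele frequency complemented), and rows that cannot
#' be matched on position + alleles are dropped with a message.
#'
#' @param sumstats data.frame in the summary-statistics dialect (see
#'   [read_sumstats()]) covering one or more cohorts.
#' @return the harmonized data.frame with a `variant` key column added.
#' @export
harmonize_sumstats <- function(sumstats) {
  locus <- paste(sumstats$chrom, sumstats$pos, sep = ":")
  first <- match(locus, locus)          # index of first row at each locus
  cref <- sumstats$ref[first]; calt <- sumstats$alt[first]
  straight <- sumstats$ref == cref & sumstats$alt == calt
  flipped <- !straight & sumstats$ref == calt & sumstats$alt == cref
  drop <- !straight & !flipped
  if (any(flipped)) {
    sumstats$beta[flipped] <- -sumstats$beta[flipped]
    sumstats$af[flipped] <- 1 - sumstats$af[flipped]
    sumstats$ref[flipped] <- cref[flipped]
    sumstats$alt[flipped] <- calt[flipped]
  }
  if (any(drop))
    message(sum(drop), " summary rows dropped: alleles not matchable")
  out <- sumstats[!drop, , drop = FALSE]
  out$variant <- paste(out$chrom, out$pos, out$ref, out$alt, sep = ":")
  out
}

#' Filter summary statistics on frequency and imputation quality
#'
#' @param sumstats summary-statistics data.frame.
#' @param min_maf minimum minor-allele frequency (default 0.0001 = 0.01%).
#' @param min_info minimum imputation info score, applied only if an `info`
#'   column is present.
#' @return the filtered data.frame; counts in/out are reported via `message`.
#' @export
filter_sumstats <- function(sumstats, min_maf = 1e-4, min_info = 0.8) {
  n0 <- nrow(sumstats)
  maf <- pmin(sumstats$af, 1 - sumstats$af)
  keep <- maf >= min_maf
  if (!is.null(sumstats$info)) keep <- keep & sumstats$info >= min_info
  out <- sumstats[keep, , drop = FALSE]
  message(sprintf("filter_sumstats: %d rows in, %d rows out", n0, nrow(out)))
  out
}

#' Meta-analyse a multi-cohort summary-statistics table
#'
#' Harmonizes the table, then runs [ivw_meta()] per variant and, when a
#' [class_thresholds()] scheme and per-variant classes are given, flags
#' class-based significance.
#'
#' @param sumstats summary-statistics data.frame (multiple cohorts).
#' @param classes optional named vector mapping variant key
#'   (`chrom:pos:ref:alt`) to class label.
#' @param scheme optional `threshold_scheme` from [class_thresholds()].
#' @return data.frame with one row per variant: pooled `beta`, `se`, `or`,
#'   `ci_lo`, `ci_hi`, `p`, `Q`, `p_het`, `k`, and `class`, `threshold`,
#'   `significant` when a scheme is supplied.
#' @export
meta_sumstats <- function(sumstats, classes = NULL, scheme = NULL) {
  h <- harmonize_sumstats(sumstats)
  vs <- unique(h$variant)
  rows <- lapply(vs, function(v) {
    d <- h[h$variant == v, ]
    m <- ivw_meta(d$beta, d$se)
    data.frame(variant = v, beta = m$beta, se = m$se, or = m$or,
               ci_lo = m$ci_lo, ci_hi = m$ci_hi, p = m$p,
               Q = m$Q, p_het = m$p_het, k = m$k)
  })
  out <- do.call(rbind, rows)
  if (!is.null(scheme)) {
    out$class <- if (is.null(classes)) scheme$class[1] else
      unname(classes[out$variant])
    out$threshold <- scheme$threshold[match(out$class, scheme$class)]
    out$significant <- out$p < out$threshold
  }
  rownames(out) <- NULL
  out
}
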