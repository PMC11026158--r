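#' Additive genotype-phenotype association
#'
#' Ordinary least squares of a (typically rank-inverse-normal transformed)
#' phenotype on allele dosage plus optional covariates, with a two-sided
#' p-value from the t distribution on the residual degrees of freedom. Rows
#' with missing phenotype, dosage or covariates are dropped.
#'
#' @param y numeric phenotype vector.
#' @param dosage allele dosage (0/1/2) vector.
#' @param covariates optional numeric matrix / data.frame of covariates.
#' @return list with `beta`, `se`, `p`, `n`. A perfect fit (zero residual
#'   variance) is reported with `se = 0` and `p = 0`.
#' @export
additive_assoc <- function(y, dosage, covariates = NULL) {
  X <- cbind(`(Intercept)` = 1, dosage = dosage)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    X <- cbind(X, covariates)
  }
  ok <- stats::complete.cases(X) & !is.na(y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  n <- length(y)
  if (n <= ncol(X) + 1L)
    stop("too few complete observations for the design", call. = FALSE)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(drop, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm.fit(X, y)
  df <- n - ncol(X)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df
  XtXinv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * XtXinv[2L, 2L])
  beta <- unname(fit$coefficients["dosage"])
  if (se == 0) return(list(beta = beta, se = 0, p = 0, n = n))
  tval <- beta / se
  list(beta = beta, se = se, p = 2 * stats::pt(-abs(tval), df), n = n)
}

#' Per-chromosome association effects
#'
#' Runs [additive_assoc()] of the rank-normalized per-chromosome phenotype on
#' dosage, one chromosome at a time, and attaches the effect in native units
#' (`beta_raw = beta * SD(raw phenotype in scope)`), mirroring the dual
#' "s.d. / raw units" reporting convention.
#'
#' @param pheno phenotype table from [compute_phenotypes()] (per-chromosome
#'   rows required); rank normalization is done here per scope.
#' @param meioses data.frame with `meiosis_id` and `dosage`.
#' @param phenotype one of `"RR"`, `"RH"`, `"TD"`, `"GC"`, `"RT"`.
#' @param covariates optional covariate matrix aligned with `meioses`.
#' @return data.frame of class `chrom_effects`: one row per chromosome with
#'   `chrom`, `phenotype`, `beta` (s.d. units), `se`, `p`, `n`, `beta_raw`,
#'   `ci_lo`, `ci_hi` (95% CI in s.d. units). Chromosomes whose phenotype is
#'   all-missing or constant are omitted with a warning.
#' @export
per_chromosome_effects <- function(pheno, meioses, phenotype = "TD",
                                   covariates = NULL) {
  stopifnot(phenotype %in% c("RR", "RH", "TD", "GC", "RT"))
  scopes <- setdiff(unique(pheno$scope), "genome")
  if (!length(scopes)) stop("no per-chromosome scopes in `pheno`", call. = FALSE)
  dos <- meioses$dosage[match(pheno$meiosis_id, meioses$meiosis_id)]
  out <- vector("list", length(scopes))
  skipped <- character(0)
  for (i in seq_along(scopes)) {
    sc <- scopes[i]
    sel <- pheno$scope == sc
    raw <- pheno[[phenotype]][sel]
    if (sum(!is.na(raw)) < 3L || stats::sd(raw, na.rm = TRUE) == 0) {
      skipped <- c(skipped, sc)
      next
    }
    yr <- rank_inverse_normal(raw)
    a <- additive_assoc(yr, dos[sel], covariates)
    out[[i]] <- data.frame(chrom = sc, phenotype = phenotype,
                           beta = a$beta, se = a$se, p = a$p, n = a$n,
                           beta_raw = a$beta * stats::sd(raw, na.rm = TRUE),
                           ci_lo = a$beta - 1.96 * a$se,
                           ci_hi = a$beta + 1.96 * a$se)
  }
  if (length(skipped))
    warning("omitted chromosome(s) with missing/constant phenotype: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("chrom_effects", "data.frame")
  res
}

#' Chromosome-length interaction regression
#'
#' Weighted linear regression of per-chromosome effect estimates on physical
#' chromosome length (Mb), with weights equal to the inverse variance of each
#' effect estimate. This is the "effect versus chromosome length" fit used to
#' test whether a variant's effect on a recombination phenotype scales with
#' chromosome size.
#'
#' @param effects a `chrom_effects` table (or any data.frame with `beta` and
#'   `se` columns and a `chrom` column matching `lengths`' names).
#' @param lengths chromosome physical lengths in Mb: a named vector, or a
#'   `genome_model` from which lengths are taken.
#' @return object of class `length_interaction`: `slope` (per Mb), `se`,
#'   `p`, `intercept`, and the underlying `lm` fit.
#' @export
length_interaction <- function(effects, lengths) {
  if (inherits(lengths, "genome_model"))
    lengths <- vapply(lengths$chromosomes, `[[`, 0, "physical_length") / 1e6
  l <- lengths[match(effects$chrom, names(lengths))]
  if (anyNA(l)) stop("missing length for chromosome(s): ",
                     paste(effects$chrom[is.na(l)], collapse = ", "),
                     call. = FALSE)
  if (any(effects$se <= 0) || any(!is.finite(effects$se)))
    stop("all effect estimates need a finite positive variance", call. = FALSE)
  if (nrow(effects) < 2L) stop("need at least 2 chromosomes", call. = FALSE)
  d <- data.frame(beta = effects$beta, l = as.numeric(l))
  d$w <- 1 / effects$se^2
  fit <- stats::lm(beta ~ l, data = d, weights = d$w)
  cf <- summary(fit)$coefficients
  slope <- cf["l", "Estimate"]
  se <- if (nrow(d) > 2L) cf["l", "Std. Error"] else NA_real_
  p <- if (nrow(d) > 2L) cf["l", "Pr(>|t|)"] else NA_real_
  structure(list(slope = slope, se = se, p = p,
                 intercept = cf["(Intercept)", "Estimate"],
                 n_chrom = nrow(d), lm = fit),
            class = "length_interaction")
}

#' @export
print.length_interaction <- function(x, ...) {
  cat("Chromosome-length interaction (inverse-variance weighted regression)\n")
  cat(sprintf("  slope     = %.4g per Mb (SE %.3g, P = %.3g)\n",
              x$slope, x$se, x$p))
  cat(sprintf("  intercept = %.4g;  %d chromosomes\n", x$intercept, x$n_chrom))
  invisible(x)
}

#' @export
coef.length_interaction <- function(object, ...)
  c(intercept = object$intercept, slope = object$slope)

#' Plot per-chromosome effects against chromosome length
#'
#' Draws the per-chromosome effect estimates with their 95% confidence
#' intervals against physical length, overlaying the weighted regression line.
#'
#' @param x a `length_interaction` object.
#' @param effects the `chrom_effects` table used in the fit.
#' @param lengths chromosome lengths (Mb), as in [length_interaction()].
#' @param ... passed to [plot()].
#' @export
plot.length_interaction <- function(x, effects, lengths, ...) {
  if (inherits(lengths, "genome_model"))
    lengths <- vapply(lengths$chromosomes, `[[`, 0, "physical_length") / 1e6
  l <- lengths[match(effects$chrom, names(lengths))]
  graphics::plot(l, effects$beta, pch = 19,
                 xlab = "chromosome length (Mb)",
                 ylab = sprintf("effect on %s (s.d.)", effects$phenotype[1]),
                 ylim = range(c(effects$ci_lo, effects$ci_hi)), ...)
  graphics::segments(l, effects$ci_lo, l, effects$ci_hi)
  graphics::abline(x$intercept, x$slope, col = "blue")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
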