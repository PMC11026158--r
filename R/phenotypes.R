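#' Per-meiosis recombination phenotypes
#'
#' Computes the five crossover-derived phenotypes for each meiosis, genome-wide
#' and (optionally) per chromosome:
#' \describe{
#'   \item{RR}{recombination rate: the number of crossovers transmitted.}
#'   \item{RH}{hotspot usage: the fraction of crossovers falling inside the
#'     chromosome's hotspot intervals (local rate at least 10 times the
#'     genome average).}
#'   \item{TD}{telomere distance: the mean, over crossovers, of the distance
#'     in bp to the nearest chromosome end divided by the chromosome length
#'     (so TD lies in [0, 0.5]); chromosome ends are bp 0 and the reference
#'     physical length.}
#'   \item{GC}{mean GC fraction in a 1,000-bp window centered on each
#'     crossover (clipped at chromosome ends).}
#'   \item{RT}{mean replication-timing score, same window convention.}
#' }
#' The four location phenotypes (RH, TD, GC, RT) are `NA` for a scope in which
#' the meiosis has no crossover; RR is 0 there.
#'
#' @param crossovers data.frame with columns `meiosis_id`, `chrom`, `pos_bp`
#'   (e.g. the `crossovers` element of [simulate_recombination_cohort()]).
#' @param genome a `genome_model`; every chromosome must carry hotspot
#'   intervals (see [call_hotspots()]) and GC/RT tracks for the corresponding
#'   phenotypes to be computed (they are `NA` otherwise).
#' @param meioses optional data.frame with a `meiosis_id` column listing the
#'   full set of meioses (so meioses without any crossover get RR = 0 rows);
#'   defaults to the ids present in `crossovers`.
#' @param per_chromosome also emit one row per (meiosis, chromosome).
#' @param window GC/RT window width in bp.
#' @return data.frame with columns `meiosis_id`, `scope` (`"genome"` or a
#'   chromosome name), `RR`, `RH`, `TD`, `GC`, `RT`.
#' @export
compute_phenotypes <- function(crossovers, genome, meioses = NULL,
                               per_chromosome = TRUE, window = 1000) {
  bad <- setdiff(unique(crossovers$chrom), names(genome$chromosomes))
  if (length(bad))
    stop("crossovers on unknown chromosome(s): ", paste(bad, collapse = ", "),
         " (first offending row ",
         which(crossovers$chrom %in% bad)[1], ")", call. = FALSE)
  ids <- if (is.null(meioses)) unique(crossovers$meiosis_id) else meioses$meiosis_id
  half <- window / 2

  # per-crossover annotations
  n <- nrow(crossovers)
  td <- hot <- gc <- rt <- rep(NA_real_, n)
  for (cn in unique(crossovers$chrom)) {
    i <- which(crossovers$chrom == cn)
    chrom <- genome$chromosomes[[cn]]
    pos <- crossovers$pos_bp[i]
    if (any(pos < 0 | pos > chrom$physical_length))
      stop(sprintf("crossover position outside %s (first offending row %d)",
                   cn, i[which(pos < 0 | pos > chrom$physical_length)[1]]),
           call. = FALSE)
    len <- chrom$physical_length
    td[i] <- pmin(pos, len - pos) / len
    hs <- chrom$hotspot_intervals
    if (!is.null(hs)) {
      if (nrow(hs)) {
        # position is hot iff it falls in [start, end): count boundary crossings
        inhot <- findInterval(pos, as.vector(t(hs))) %% 2L == 1L
        hot[i] <- as.numeric(inhot)
      } else hot[i] <- 0
    }
    s <- pmax(pos - half, 0); e <- pmin(pos + half, len)
    if (!is.null(chrom$gc_track)) gc[i] <- track_mean(chrom$gc_track, s, e)
    if (!is.null(chrom$rt_track)) rt[i] <- track_mean(chrom$rt_track, s, e)
  }

  gidx_all <- match(as.character(crossovers$meiosis_id), as.character(ids))
  if (anyNA(gidx_all))
    stop("crossover rows for meioses absent from `meioses`", call. = FALSE)
  nlev <- length(ids)
  group_mean <- function(v, gidx) {
    ok <- !is.na(v)
    s <- cntv <- rep(0, nlev)
    if (any(ok)) {
      r <- rowsum(v[ok], gidx[ok])
      s[as.integer(rownames(r))] <- r[, 1L]
      c2 <- rowsum(rep(1, sum(ok)), gidx[ok])
      cntv[as.integer(rownames(c2))] <- c2[, 1L]
    }
    ifelse(cntv > 0, s / cntv, NA_real_)
  }
  agg <- function(sel, scope) {
    gi <- gidx_all[sel]
    data.frame(meiosis_id = ids, scope = scope,
               RR = tabulate(gi, nlev),
               RH = group_mean(hot[sel], gi), TD = group_mean(td[sel], gi),
               GC = group_mean(gc[sel], gi), RT = group_mean(rt[sel], gi))
  }
  res <- list(agg(rep(TRUE, n), "genome"))
  if (per_chromosome)
    for (cn in names(genome$chromosomes))
      res[[length(res) + 1L]] <- agg(crossovers$chrom == cn, cn)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Rank-based inverse-normal transformation
#'
#' Replaces the non-missing values of `x` by standard-normal quantiles of
#' their offset ranks, `qnorm((rank - 0.5) / m)` with average ranks for ties
#' and `m` the number of non-missing values. Missing values stay missing.
#' The result is invariant under any strictly monotone transformation of the
#' input.
#'
#' @param x numeric vector, possibly with `NA`s; at least 2 non-missing
#'   values are required.
#' @return the transformed vector (mean approximately 0, SD approximately 1).
#' @export
rank_inverse_normal <- function(x) {
  m <- sum(!is.na(x))
  if (m < 2L) stop("need at least 2 non-missing values", call. = FALSE)
  r <- rank(x, na.last = "keep", ties.method = "average")
  stats::qnorm((r - 0.5) / m)
}

#' Add rank-inverse-normal columns to a phenotype table
#'
#' Applies [rank_inverse_normal()] to each phenotype column within each scope,
#' producing `<pheno>_rin` columns. Missing values (meioses with no crossover
#' in scope, for location phenotypes) are dropped per-phenotype before
#' ranking and remain missing.
#'
#' @param pheno a phenotype table from [compute_phenotypes()].
#' @param phenotypes which columns to transform.
#' @return the table with `_rin` columns appended.
#' @export
add_rin <- function(pheno, phenotypes = c("RR", "RH", "TD", "GC", "RT")) {
  for (ph in phenotypes) {
    v <- rep(NA_real_, nrow(pheno))
    for (sc in unique(pheno$scope)) {
      i <- pheno$scope == sc
      if (sum(!is.na(pheno[[ph]][i])) >= 2L)
        v[i] <- rank_inverse_normal(pheno[[ph]][i])
    }
    pheno[[paste0(ph, "_rin")]] <- v
  }
  pheno
}

#' Filter meioses by their crossover count on one chromosome
#'
#' Splits a cohort by whether a meiosis transmitted exactly one, or more than
#' one, crossover on the given chromosome. Together with the zero-crossover
#' meioses the two modes partition the cohort.
#'
#' @param meioses data.frame with a `meiosis_id` column (all meioses).
#' @param crossovers crossover data.frame.
#' @param chrom chromosome name.
#' @param mode `"exactly_one"` or `"more_than_one"`.
#' @return the subset of `meioses` rows matching the mode.
#' @export
filter_by_crossover_count <- function(meioses, crossovers, chrom,
                                      mode = c("exactly_one", "more_than_one")) {
  mode <- match.arg(mode)
  cnt <- table(factor(as.character(
    crossovers$meiosis_id[crossovers$chrom == chrom]),
    levels = as.character(meioses$meiosis_id)))
  keep <- if (mode == "exactly_one") cnt == 1L else cnt > 1L
  meioses[as.vector(keep), , drop = FALSE]
}
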