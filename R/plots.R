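#' Carrier versus noncarrier mean telomere distance
#'
#' For each chromosome, plots the mean TD of noncarrier meioses (x axis)
#' against carrier meioses (y axis) with seeded bootstrap 95% confidence
#' bars; points below the identity line indicate crossovers shifted toward
#' the telomeres in carriers. Purely descriptive; inference comes from
#' [per_chromosome_effects()] and [length_interaction()].
#'
#' @param pheno phenotype table from [compute_phenotypes()] with
#'   per-chromosome scopes.
#' @param meioses data.frame with `meiosis_id` and `dosage`.
#' @param n_boot bootstrap resamples for the CI bars.
#' @param seed seed for the bootstrap (caller's RNG preserved).
#' @param ... passed to [plot()].
#' @return invisibly, the per-chromosome summary data.frame (`chrom`,
#'   `td_noncarrier`, `td_carrier` and the carrier CI bounds).
#' @export
plot_td_scatter <- function(pheno, meioses, n_boot = 2000, seed = 1, ...) {
  per <- pheno[pheno$scope != "genome" & !is.na(pheno$TD), ]
  carrier <- meioses$dosage[match(per$meiosis_id, meioses$meiosis_id)] > 0
  sm <- with_seed(seed, {
    do.call(rbind, lapply(unique(per$scope), function(cn) {
      i <- per$scope == cn
      tdc <- per$TD[i & carrier]; tdn <- per$TD[i & !carrier]
      bs <- vapply(seq_len(n_boot), function(b)
        mean(sample(tdc, replace = TRUE)), 0)
      data.frame(chrom = cn, td_noncarrier = mean(tdn),
                 td_carrier = mean(tdc),
                 ci_lo = stats::quantile(bs, 0.025),
                 ci_hi = stats::quantile(bs, 0.975))
    }))
  })
  rng <- range(c(sm$td_noncarrier, sm$ci_lo, sm$ci_hi))
  graphics::plot(sm$td_noncarrier, sm$td_carrier, pch = 19,
                 xlim = rng, ylim = rng,
                 xlab = "mean TD, noncarriers", ylab = "mean TD, carriers",
                 ...)
  graphics::segments(sm$td_noncarrier, sm$ci_lo, sm$td_noncarrier, sm$ci_hi)
  graphics::abline(0, 1, lty = 2)
  invisible(sm)
}
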