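#' Simulate crossover positions under the Housworth-Stahl process
#'
#' Draws crossover genetic positions on `[0, L]` as the union of two
#' independent processes: (a) the interference pathway, a stationary gamma
#' renewal chiasma process with shape `nu` and rate `2*nu*(1-p)` per Morgan,
#' each chiasma retained on the simulated product with probability 1/2;
#' (b) the escape pathway, a Poisson process with rate `p` per Morgan.
#' Stationarity of the renewal process is achieved by burn-in: the process is
#' started `burnin` mean inter-chiasma gaps to the left of the interval. The
#' combined crossover intensity is exactly 1 per Morgan for every (`nu`, `p`).
#'
#' @param params a [stahl_params()] object.
#' @param L interval genetic length in Morgans (> 0).
#' @param n number of independent replicates.
#' @param burnin burn-in length in units of mean inter-chiasma gaps.
#' @return for `n = 1` a sorted numeric vector of positions (Morgans);
#'   otherwise a list of `n` such vectors.
#' @export
simulate_stahl_process <- function(params, L, n = 1L, burnin = 20) {
  stopifnot_scalar(L, "L", lo = .Machine$double.xmin)
  nu <- params$nu; p <- params$p
  n <- as.integer(n)
  # escape pathway (flat vectors: position + replicate id)
  ne <- stats::rpois(n, p * L)
  all_pos <- stats::runif(sum(ne), 0, L)
  all_id <- rep.int(seq_len(n), ne)
  if (p < 1) {
    rate <- 2 * nu * (1 - p)
    mean_gap <- nu / rate                       # = 1 / (2 (1 - p))
    span <- burnin * mean_gap + L
    m_exp <- span / mean_gap
    ncol0 <- as.integer(ceiling(m_exp + 6 * sqrt(m_exp) + 10))
    draw_block <- function(nrep, ncols, offset) {
      # gaps in rows, replicates in columns: accumulate row by row so the
      # cumulative sum stays vectorized across replicates
      g <- matrix(stats::rgamma(nrep * ncols, shape = nu, rate = rate),
                  nrow = ncols)
      g[1L, ] <- g[1L, ] + offset
      for (i in seq_len(ncols)[-1L]) g[i, ] <- g[i, ] + g[i - 1L, ]
      g
    }
    cs <- draw_block(n, ncol0, rep(0, n))
    tot <- cs[nrow(cs), ]
    # top up replicates whose chiasma trail has not yet crossed the interval
    while (any(short <- tot < span)) {
      add <- draw_block(sum(short), as.integer(ceiling(0.3 * ncol0)) + 5L,
                        tot[short])
      cs2 <- matrix(NA_real_, nrow(cs) + nrow(add), n)
      cs2[seq_len(nrow(cs)), ] <- cs
      cs2[-seq_len(nrow(cs)), short] <- add
      cs <- cs2
      tot[short] <- add[nrow(add), ]
    }
    b <- burnin * mean_gap
    keep <- which(!is.na(cs) & cs > b & cs <= b + L &
                    stats::runif(length(cs)) < 0.5)
    all_pos <- c(all_pos, cs[keep] - b)
    all_id <- c(all_id, ((keep - 1L) %/% nrow(cs)) + 1L)
  }
  o <- order(all_id, all_pos)
  out <- split(all_pos[o], factor(all_id[o], levels = seq_len(n)))
  names(out) <- NULL
  if (n == 1L) out[[1L]] else out
}

#' Carrier effect specification for the simulator
#'
#' Describes how the focal allele changes the crossover process:
#' dosage-specific Housworth-Stahl parameters (the heterozygote defaults to
#' the midpoint of the two homozygote parameter sets, i.e. an additive model
#' on the parameter scale) and an optional "distal shift", a monotone warp of
#' the genetic map toward the chromosome ends that moves carrier crossovers
#' closer to the telomeres while preserving each chromosome's total map
#' length. The warp strength on a chromosome of physical length `l` Mb is
#' `theta = distal_a + distal_b * l` (clamped at 0), scaled by `dosage / 2`.
#'
#' @param params0 [stahl_params()] for dosage 0 (noncarrier homozygote).
#' @param params2 [stahl_params()] for dosage 2; defaults to `params0`.
#' @param params1 optional explicit heterozygote parameters (default:
#'   midpoint of `params0` and `params2`).
#' @param distal_a,distal_b intercept and per-Mb slope of the distal-shift
#'   strength.
#' @return an object of class `carrier_effect_spec`.
#' @export
carrier_effect_spec <- function(params0, params2 = NULL, params1 = NULL,
                                distal_a = 0, distal_b = 0) {
  if (is.null(params2)) params2 <- params0
  if (is.null(params1))
    params1 <- stahl_params((params0$nu + params2$nu) / 2,
                            (params0$p + params2$p) / 2)
  structure(list(params_by_dosage = list(params0, params1, params2),
                 distal_a = distal_a, distal_b = distal_b),
            class = "carrier_effect_spec")
}

# Monotone warp of a normalized position u in [0, 1] toward the interval
# ends, preserving the endpoints: on each half the position is mapped through
# a power function with exponent 1 + theta (theta >= 0 pushes toward 0 / 1).
.distal_warp <- function(u, theta) {
  if (theta <= 0) return(u)
  c <- 1 + theta
  ifelse(u <= 0.5, 0.5 * (2 * u)^c, 1 - 0.5 * (2 * (1 - u))^c)
}

#' Simulate a cohort of meioses with transmitted crossovers
#'
#' Parent dosages of the focal allele are drawn under Hardy-Weinberg
#' equilibrium, `dosage ~ Binomial(2, allele_frequency)`; each meiosis then
#' receives crossovers per chromosome from the dosage-specific Stahl process
#' of `spec`, optionally warped toward the telomeres, and genetic positions
#' are converted to physical coordinates through the genome's map.
#'
#' @param n_meioses number of meioses.
#' @param allele_frequency focal-allele frequency in [0, 1].
#' @param spec a [carrier_effect_spec()].
#' @param genome a `genome_model`.
#' @param seed seed controlling all randomness (caller's RNG preserved).
#' @return a list of class `recomb_cohort` with `meioses` (data.frame:
#'   `meiosis_id`, `dosage`) and `crossovers` (data.frame: `meiosis_id`,
#'   `dosage`, `chrom`, `pos_bp`, `pos_cM`, sorted by meiosis, chromosome and
#'   position).
#' @export
simulate_recombination_cohort <- function(n_meioses, allele_frequency, spec,
                                          genome, seed = NULL) {
  stopifnot_scalar(allele_frequency, "allele_frequency", lo = 0, hi = 1)
  if (n_meioses < 1) stop("n_meioses must be >= 1", call. = FALSE)
  with_seed(seed, {
    dosage <- stats::rbinom(n_meioses, 2L, allele_frequency)
    ids <- seq_len(n_meioses)
    glen <- genetic_length(genome, "morgans")
    out <- vector("list", 3L * length(glen))
    k <- 0L
    for (d in 0:2) {
      who <- ids[dosage == d]
      if (!length(who)) next
      pars <- spec$params_by_dosage[[d + 1L]]
      for (cn in names(glen)) {
        chrom <- genome$chromosomes[[cn]]
        Lm <- glen[[cn]]
        draws <- simulate_stahl_process(pars, Lm, n = length(who))
        if (length(who) == 1L) draws <- list(draws)
        nxo <- lengths(draws)
        if (!sum(nxo)) next
        g <- unlist(draws, use.names = FALSE)          # Morgans
        theta <- max(0, (spec$distal_a +
                           spec$distal_b * chrom$physical_length / 1e6)) * d / 2
        g <- .distal_warp(g / Lm, theta) * Lm
        cm <- pmin(g * 100, max(chrom$map_anchors$cM))  # guard fp overshoot
        bp <- map_convert(chrom, cm, "gen2phys")
        k <- k + 1L
        out[[k]] <- data.frame(meiosis_id = rep.int(who, nxo),
                               dosage = d, chrom = cn,
                               pos_bp = round(bp), pos_cM = cm)
      }
    }
    xo <- do.call(rbind, out[seq_len(k)])
    if (is.null(xo))
      xo <- data.frame(meiosis_id = integer(0), dosage = integer(0),
                       chrom = character(0), pos_bp = numeric(0),
                       pos_cM = numeric(0))
    xo <- xo[order(xo$meiosis_id, xo$chrom, xo$pos_bp), , drop = FALSE]
    rownames(xo) <- NULL
    structure(list(meioses = data.frame(meiosis_id = ids, dosage = dosage),
                   crossovers = xo),
              class = "recomb_cohort")
  })
}

#' @export
print.recomb_cohort <- function(x, ...) {
  cat(sprintf("recomb_cohort: %d meioses (%d carrier), %d crossovers\n",
              nrow(x$meioses), sum(x$meioses$dosage > 0), nrow(x$crossovers)))
  invisible(x)
}

#' Simulate a single meiosis
#'
#' Convenience wrapper around [simulate_recombination_cohort()] drawing one
#' meiosis at a fixed dosage.
#'
#' @param genome a `genome_model`.
#' @param spec a [carrier_effect_spec()].
#' @param dosage 0, 1 or 2 copies of the focal allele.
#' @param seed optional seed.
#' @return a data.frame of crossovers (`chrom`, `pos_bp`, `pos_cM`) with the
#'   dosage as attribute `"dosage"`.
#' @export
simulate_meiosis <- function(genome, spec, dosage = 0L, seed = NULL) {
  if (!dosage %in% 0:2) stop("dosage must be 0, 1 or 2", call. = FALSE)
  # draw at the dosage-specific parameters, then apply the warp at `dosage`
  fixed <- carrier_effect_spec(spec$params_by_dosage[[dosage + 1L]])
  co <- with_seed(seed, simulate_recombination_cohort(1L, 0, fixed,
                                                      genome)$crossovers)
  if (dosage > 0 && (spec$distal_a != 0 || spec$distal_b != 0)) {
    # redo warp at the requested dosage on the genetic scale
    for (cn in unique(co$chrom)) {
      chrom <- genome$chromosomes[[cn]]
      G <- max(chrom$map_anchors$cM)
      theta <- max(0, spec$distal_a +
                     spec$distal_b * chrom$physical_length / 1e6) * dosage / 2
      i <- co$chrom == cn
      cm <- .distal_warp(co$pos_cM[i] / G, theta) * G
      co$pos_cM[i] <- cm
      co$pos_bp[i] <- round(map_convert(chrom, cm, "gen2phys"))
    }
  }
  out <- co[order(co$chrom, co$pos_bp), c("chrom", "pos_bp", "pos_cM")]
  rownames(out) <- NULL
  attr(out, "dosage") <- dosage
  out
}

#' Simulate case-control cohorts with a specified per-allele odds ratio
#'
#' Genotypes are drawn `Binomial(2, freq)`; case status is Bernoulli with
#' `logit P(case) = alpha_c + dosage * log(true_or)` where the per-cohort
#' intercept `alpha_c` is calibrated by 1-D root finding so that the expected
#' case fraction equals `n_cases / (n_cases + n_controls)`.
#'
#' @param n_cases,n_controls integer vectors (one entry per cohort) of target
#'   case and control counts; realized counts vary binomially around them.
#' @param allele_freqs risk-allele frequency per cohort, in (0, 1).
#' @param true_or per-allele odds ratio (> 0).
#' @param seed seed controlling all randomness.
#' @return data.frame with columns `id`, `dosage`, `status` (1 = case),
#'   `cohort`.
#' @export
simulate_case_control_cohorts <- function(n_cases, n_controls, allele_freqs,
                                          true_or, seed = NULL) {
  stopifnot_scalar(true_or, "true_or", lo = .Machine$double.xmin)
  k <- length(n_cases)
  if (length(n_controls) != k || length(allele_freqs) != k)
    stop("n_cases, n_controls and allele_freqs must have equal length",
         call. = FALSE)
  if (any(allele_freqs <= 0 | allele_freqs >= 1))
    stop("allele frequencies must be in (0, 1)", call. = FALSE)
  b <- log(true_or)
  with_seed(seed, {
    res <- vector("list", k)
    for (c in seq_len(k)) {
      n <- n_cases[c] + n_controls[c]
      target <- n_cases[c] / n
      q <- allele_freqs[c]
      pd <- stats::dbinom(0:2, 2L, q)
      fr <- function(a) sum(pd * stats::plogis(a + (0:2) * b)) - target
      if (fr(-35) > 0 || fr(35) < 0)
        stop("requested case fraction is not attainable", call. = FALSE)
      alpha <- stats::uniroot(fr, c(-35, 35), tol = 1e-10)$root
      dosage <- stats::rbinom(n, 2L, q)
      status <- stats::rbinom(n, 1L, stats::plogis(alpha + dosage * b))
      res[[c]] <- data.frame(id = seq_len(n), dosage = dosage, status = status,
                             cohort = paste0("cohort", c))
    }
    do.call(rbind, res)
  })
}
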