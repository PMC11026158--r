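#' Pipeline run configuration
#'
#' Validates and normalizes the configuration driving [run_pipeline()]. The
#' configuration can also be loaded from a YAML/JSON-like list (e.g.
#' `yaml::read_yaml(path)`) and passed straight in.
#'
#' @param seed mandatory seed; every stochastic stage derives its stream from
#'   it.
#' @param genome either a `genome_model` or a list of arguments for
#'   [synthetic_genome()].
#' @param n_meioses,allele_frequency recombination-cohort size and focal
#'   allele frequency.
#' @param params0,params2 noncarrier / carrier-homozygote Stahl parameters as
#'   `c(nu, p)`.
#' @param distal_a,distal_b distal-shift strength (intercept, per-Mb slope).
#' @param phenotypes which phenotypes to associate.
#' @param do_phenotypes,do_assoc,do_interference,do_meta stage toggles.
#' @param meta list with `n_cases`, `n_controls`, `allele_freqs`, `true_or`
#'   for the case-control stage.
#' @param interference_control optimizer control forwarded to [fit_stahl()].
#' @return validated list of class `run_config`.
#' @export
run_config <- function(seed,
                       genome = list(n_chrom = 3),
                       n_meioses = 500,
                       allele_frequency = 0.2,
                       params0 = c(6.59, 0.039),
                       params2 = c(5.97, 0.045),
                       distal_a = 0, distal_b = 0,
                       phenotypes = c("TD", "RR"),
                       do_phenotypes = TRUE, do_assoc = TRUE,
                       do_interference = TRUE, do_meta = TRUE,
                       meta = list(n_cases = c(500, 500),
                                   n_controls = c(2000, 2000),
                                   allele_freqs = c(0.01, 0.008),
                                   true_or = 1.22),
                       interference_control = list()) {
  stopifnot_scalar(seed, "seed")
  if (!inherits(genome, "genome_model")) {
    if (!is.list(genome)) stop("`genome` must be a genome_model or a list",
                               call. = FALSE)
  }
  stopifnot_scalar(n_meioses, "n_meioses", lo = 1)
  stopifnot_scalar(allele_frequency, "allele_frequency", lo = 0, hi = 1)
  as_sp <- function(x) if (inherits(x, "stahl_params")) x else
    stahl_params(x[1], x[2])
  cfg <- list(seed = as.integer(seed), genome = genome,
              n_meioses = as.integer(n_meioses),
              allele_frequency = allele_frequency,
              params0 = as_sp(params0),
              params2 = as_sp(params2),
              distal_a = distal_a, distal_b = distal_b,
              phenotypes = match.arg(phenotypes,
                                     c("RR", "RH", "TD", "GC", "RT"),
                                     several.ok = TRUE),
              do_phenotypes = isTRUE(do_phenotypes),
              do_assoc = isTRUE(do_assoc),
              do_interference = isTRUE(do_interference),
              do_meta = isTRUE(do_meta),
              meta = meta,
              interference_control = interference_control)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes simulate -> phenotypes -> association (+ per-chromosome effects
#' and chromosome-length interaction) -> interference fitting (+ carrier/
#' noncarrier likelihood-ratio test) -> case-control meta-analysis, writing
#' every intermediate table as a TSV with a provenance header and returning a
#' manifest of the emitted files with checksums. All randomness derives from
#' `config$seed`, so identical configurations produce identical artifacts.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results and the
#'   `manifest` data.frame (`file`, `md5`, `bytes`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "run_config")) stop("`config` must be a run_config",
                                            call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- sprintf("seed=%d | meiorec %s", config$seed,
                  as.character(utils::packageVersion("meiorec")))
  emitted <- character(0)
  emit <- function(x, name, extra = NULL) {
    p <- file.path(out_dir, name)
    .write_tsv(x, p, c(prov, extra))
    emitted <<- c(emitted, p)
    p
  }
  res <- list(config = config)

  genome <- if (inherits(config$genome, "genome_model")) config$genome else
    do.call(synthetic_genome, c(config$genome, list(seed = config$seed)))
  res$genome <- genome

  spec <- carrier_effect_spec(config$params0, config$params2,
                              distal_a = config$distal_a,
                              distal_b = config$distal_b)
  cohort <- simulate_recombination_cohort(config$n_meioses,
                                          config$allele_frequency, spec,
                                          genome, seed = config$seed + 1L)
  res$cohort <- cohort
  emit(cohort$crossovers, "crossovers.tsv")
  emit(cohort$meioses, "meioses.tsv")

  if (config$do_phenotypes) {
    pheno <- add_rin(compute_phenotypes(cohort$crossovers, genome,
                                        meioses = cohort$meioses))
    res$phenotypes <- pheno
    emit(pheno, "phenotypes.tsv")
  }

  if (config$do_assoc) {
    if (!config$do_phenotypes)
      stop("association stage requires the phenotype stage", call. = FALSE)
    pheno <- res$phenotypes
    dosv <- cohort$meioses$dosage[match(
      pheno$meiosis_id[pheno$scope == "genome"], cohort$meioses$meiosis_id)]
    gw <- do.call(rbind, lapply(config$phenotypes, function(ph) {
      a <- additive_assoc(pheno[[paste0(ph, "_rin")]][pheno$scope == "genome"],
                          dosv)
      data.frame(phenotype = ph, beta = a$beta, se = a$se, p = a$p, n = a$n)
    }))
    res$assoc_genomewide <- gw
    emit(gw, "assoc_genomewide.tsv")
    eff <- lapply(config$phenotypes, function(ph)
      per_chromosome_effects(pheno, cohort$meioses, ph))
    names(eff) <- config$phenotypes
    res$chrom_effects <- eff
    emit(do.call(rbind, eff), "chrom_effects.tsv")
    ia <- lapply(eff, function(e)
      if (nrow(e) >= 3L) length_interaction(e, genome) else NULL)
    res$length_interaction <- ia
    ia_tab <- do.call(rbind, lapply(names(ia), function(ph)
      if (!is.null(ia[[ph]]))
        data.frame(phenotype = ph, slope = ia[[ph]]$slope, se = ia[[ph]]$se,
                   p = ia[[ph]]$p, intercept = ia[[ph]]$intercept)))
    if (!is.null(ia_tab)) emit(ia_tab, "length_interaction.tsv")
  }

  if (config$do_interference) {
    xo <- cohort$crossovers
    car_ids <- cohort$meioses$meiosis_id[cohort$meioses$dosage > 0]
    non_ids <- cohort$meioses$meiosis_id[cohort$meioses$dosage == 0]
    mk <- function(idset) stahl_data(xo[xo$meiosis_id %in% idset, ], genome,
                                     meiosis_ids = idset)
    if (length(car_ids) && length(non_ids)) {
      lrt <- carrier_lrt(mk(car_ids), mk(non_ids),
                         control = config$interference_control)
      res$lrt <- lrt
      fits <- list(carrier = lrt$fit_carrier, noncarrier = lrt$fit_noncarrier,
                   pooled = lrt$fit_pooled)
      emit(data.frame(chi2 = lrt$chi2, df = lrt$df, p = lrt$p_value),
           "interference_lrt.tsv")
    } else {
      fits <- list(pooled = fit_stahl(mk(cohort$meioses$meiosis_id),
                                      control = config$interference_control))
      res$fit_pooled <- fits$pooled
    }
    ftab <- do.call(rbind, lapply(names(fits), function(g)
      data.frame(group = g, nu_hat = fits[[g]]$nu, p_hat = fits[[g]]$p,
                 loglik = fits[[g]]$loglik, n_meioses = fits[[g]]$n_meioses,
                 converged = fits[[g]]$converged)))
    emit(ftab, "interference_fits.tsv")
  }

  if (config$do_meta) {
    m <- config$meta
    cc <- simulate_case_control_cohorts(m$n_cases, m$n_controls,
                                        m$allele_freqs, m$true_or,
                                        seed = config$seed + 2L)
    ss <- do.call(rbind, lapply(split(cc, cc$cohort), function(d) {
      a <- logistic_assoc(d$dosage, d$status)
      data.frame(chrom = "chr19", pos = 12609775L, ref = "C", alt = "T",
                 beta = a$beta, se = a$se, p = a$p,
                 af = mean(d$dosage) / 2, n_cases = a$n_cases,
                 n_controls = a$n_controls, cohort = d$cohort[1])
    }))
    rownames(ss) <- NULL
    res$sumstats <- ss
    p <- file.path(out_dir, "sumstats.tsv")
    write_sumstats(ss, p, prov)
    emitted <- c(emitted, p)
    meta <- ivw_meta(ss$beta, ss$se)
    res$meta <- meta
    emit(data.frame(beta = meta$beta, se = meta$se, or = meta$or,
                    ci_lo = meta$ci_lo, ci_hi = meta$ci_hi, p = meta$p,
                    Q = meta$Q, p_het = meta$p_het, k = meta$k),
         "meta_result.tsv")
  }

  manifest <- data.frame(file = basename(emitted),
                         md5 = unname(tools::md5sum(emitted)),
                         bytes = file.size(emitted))
  .write_tsv(manifest, file.path(out_dir, "manifest.tsv"), prov)
  res$manifest <- manifest
  invisible(res)
}
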