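# TSV dialects. All writers emit '#'-prefixed provenance comment lines
# followed by a header row; all readers skip comment lines and are
# column-order agnostic (header-driven).

.write_tsv <- function(x, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(paste0("# ", provenance), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path, required) {
  x <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(required, names(x))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  x
}

#' Read / write crossover tables
#'
#' The crossover dialect is a TSV with header columns `meiosis_id`, `dosage`,
#' `chrom`, `pos_bp`, `pos_cM` (any column order; `#` comment lines allowed).
#' Crossovers must be sorted by increasing position within each
#' (meiosis, chromosome); if a `genome` is given, positions are validated
#' against the chromosome spans and unknown chromosomes are an error, with
#' offending line numbers reported.
#'
#' @param path file path.
#' @param genome optional `genome_model` for validation.
#' @return data.frame in the crossover dialect.
#' @export
read_crossovers <- function(path, genome = NULL) {
  x <- .read_tsv(path, c("meiosis_id", "dosage", "chrom", "pos_bp", "pos_cM"))
  x <- x[, c("meiosis_id", "dosage", "chrom", "pos_bp", "pos_cM")]
  key <- paste(x$meiosis_id, x$chrom, sep = "\r")
  ord_ok <- ave(x$pos_cM, key, FUN = function(v) c(1, diff(v)) > 0)
  if (any(ord_ok == 0))
    stop(sprintf("%s: crossovers not sorted strictly increasing (row %d)",
                 path, which(ord_ok == 0)[1]), call. = FALSE)
  if (!is.null(genome)) {
    bad <- !x$chrom %in% names(genome$chromosomes)
    if (any(bad))
      stop(sprintf("%s: unknown chromosome '%s' (row %d)", path,
                   x$chrom[which(bad)[1]], which(bad)[1]), call. = FALSE)
    len <- vapply(genome$chromosomes, `[[`, 0, "physical_length")[x$chrom]
    out <- x$pos_bp < 0 | x$pos_bp > len
    if (any(out))
      stop(sprintf("%s: pos_bp beyond chromosome length (row %d)", path,
                   which(out)[1]), call. = FALSE)
  }
  x
}

#' @rdname read_crossovers
#' @param crossovers crossover data.frame (e.g. from
#'   [simulate_recombination_cohort()]).
#' @param provenance optional character vector written as comment lines.
#' @export
write_crossovers <- function(crossovers, path, provenance = NULL) {
  .write_tsv(crossovers[, c("meiosis_id", "dosage", "chrom", "pos_bp", "pos_cM")],
             path, provenance)
}

#' Read / write GWAS summary statistics
#'
#' TSV with columns `chrom`, `pos` (1-based, the usual summary-statistics
#' convention), `ref`, `alt`, `beta`, `se`, `p`, `af`, `n_cases`,
#' `n_controls`, `cohort`.
#'
#' @param path file path.
#' @return data.frame in the summary-statistics dialect.
#' @export
read_sumstats <- function(path) {
  .read_tsv(path, c("chrom", "pos", "ref", "alt", "beta", "se", "p", "af",
                    "n_cases", "n_controls", "cohort"))
}

#' @rdname read_sumstats
#' @param sumstats summary-statistics data.frame.
#' @param provenance optional comment lines.
#' @export
write_sumstats <- function(sumstats, path, provenance = NULL) {
  .write_tsv(sumstats, path,
             c("positions are 1-based", provenance))
}

#' Read genome-definition files
#'
#' `read_chrom_sizes`: 2-column TSV (`name`, `length_bp`).
#' `read_genetic_map`: TSV (`chrom`, `pos_bp`, `cM`).
#' `read_hotspots_bed`: BED (0-based half-open: `chrom`, `start`, `end`).
#' `read_track_bedgraph`: bedGraph-style TSV (`chrom`, `start`, `end`,
#' `value`).
#'
#' @param path file path.
#' @return data.frame per dialect.
#' @export
read_chrom_sizes <- function(path) {
  x <- utils::read.delim(path, header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE)[, 1:2]
  names(x) <- c("name", "length_bp")
  x
}

#' @rdname read_chrom_sizes
#' @export
read_genetic_map <- function(path) .read_tsv(path, c("chrom", "pos_bp", "cM"))

#' @rdname read_chrom_sizes
#' @export
read_hotspots_bed <- function(path) {
  x <- utils::read.delim(path, header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE)[, 1:3]
  names(x) <- c("chrom", "start", "end")
  x
}

#' @rdname read_chrom_sizes
#' @export
read_track_bedgraph <- function(path) {
  x <- utils::read.delim(path, header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE)[, 1:4]
  names(x) <- c("chrom", "start", "end", "value")
  x
}

#' Build a genome model from standard files
#'
#' @param chrom_sizes path to a chromosome-sizes TSV.
#' @param genetic_map path to a genetic-map TSV (bp/cM anchors per
#'   chromosome; anchors at bp 0 and at the chromosome end are required).
#' @param hotspots optional BED of hotspot intervals; when absent, hotspots
#'   are called from the map at the 10-fold threshold.
#' @param gc_track,rt_track optional bedGraph tracks.
#' @return a `genome_model`.
#' @export
genome_from_files <- function(chrom_sizes, genetic_map, hotspots = NULL,
                              gc_track = NULL, rt_track = NULL) {
  sizes <- read_chrom_sizes(chrom_sizes)
  map <- read_genetic_map(genetic_map)
  hs <- if (!is.null(hotspots)) read_hotspots_bed(hotspots)
  gc <- if (!is.null(gc_track)) read_track_bedgraph(gc_track)
  rt <- if (!is.null(rt_track)) read_track_bedgraph(rt_track)
  chroms <- lapply(seq_len(nrow(sizes)), function(i) {
    nm <- sizes$name[i]
    m <- map[map$chrom == nm, ]
    if (!nrow(m)) stop("no map anchors for ", nm, call. = FALSE)
    pick <- function(d) if (is.null(d)) NULL else {
      dd <- d[d$chrom == nm, setdiff(names(d), "chrom"), drop = FALSE]
      if (nrow(dd)) dd else NULL
    }
    hh <- pick(hs)
    chromosome_model(nm, sizes$length_bp[i],
                     data.frame(bp = m$pos_bp, cM = m$cM),
                     hotspot_intervals = hh, gc_track = pick(gc),
                     rt_track = pick(rt))
  })
  g <- genome_model(chroms)
  if (is.null(hs)) g <- call_hotspots(g)
  g
}

#' GRCh38 autosome lengths
#'
#' Returns the physical lengths (bp) of the 22 human autosomes in the GRCh38
#' reference, bundled as a plain-text fixture for building realistically
#' sized genome models.
#'
#' @return data.frame with `name` and `length_bp`.
#' @export
grch38_autosome_lengths <- function() {
  read_chrom_sizes(system.file("extdata", "grch38_autosomes.tsv",
                               package = "meiorec", mustWork = TRUE))
}
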