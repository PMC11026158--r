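#' Chromosome model
#'
#' A chromosome is described by its physical length (bp, GRCh38-style
#' coordinates: 0-based, half-open intervals), a monotone genetic map given as
#' (bp, cM) anchor pairs, and optional annotation layers: hotspot intervals,
#' a GC-content track and a replication-timing track.
#'
#' @param name chromosome name (e.g. `"chr1"`).
#' @param physical_length chromosome length in bp.
#' @param map_anchors data.frame with columns `bp` and `cM`; strictly
#'   increasing in `bp`, non-decreasing in `cM`, first anchor at (0, 0) and
#'   last anchor at `physical_length` so the whole chromosome is mappable.
#' @param hotspot_intervals optional two-column matrix/data.frame of 0-based
#'   half-open `[start, end)` intervals within the chromosome.
#' @param gc_track,rt_track optional data.frames with columns `start`, `end`,
#'   `value`; bins must be contiguous and cover `[0, physical_length)`.
#'   GC values must lie in [0, 1].
#' @return an object of class `chromosome_model`.
#' @export
chromosome_model <- function(name, physical_length, map_anchors,
                             hotspot_intervals = NULL,
                             gc_track = NULL, rt_track = NULL) {
  stopifnot_scalar(physical_length, "physical_length", lo = 1)
  ma <- as.data.frame(map_anchors)
  if (!all(c("bp", "cM") %in% names(ma)))
    stop("map_anchors needs columns `bp` and `cM`", call. = FALSE)
  ma <- ma[order(ma$bp), c("bp", "cM")]
  if (nrow(ma) < 2L) stop("need at least 2 map anchors", call. = FALSE)
  if (any(diff(ma$bp) <= 0)) stop("map anchors must be strictly increasing in bp",
                                  call. = FALSE)
  if (any(diff(ma$cM) < 0)) stop("map anchors must be non-decreasing in cM",
                                 call. = FALSE)
  if (ma$bp[1] != 0 || ma$cM[1] != 0)
    stop("first map anchor must be at bp 0 / cM 0", call. = FALSE)
  if (ma$bp[nrow(ma)] != physical_length)
    stop("last map anchor must be at physical_length (map must span the chromosome)",
         call. = FALSE)
  chk_track <- function(tr, what, unit01 = FALSE) {
    if (is.null(tr)) return(NULL)
    tr <- as.data.frame(tr)
    if (!all(c("start", "end", "value") %in% names(tr)))
      stop(sprintf("%s track needs columns start, end, value", what), call. = FALSE)
    tr <- tr[order(tr$start), c("start", "end", "value")]
    if (tr$start[1] != 0 || tr$end[nrow(tr)] < physical_length ||
        any(tr$start[-1] != tr$end[-nrow(tr)]))
      stop(sprintf("%s track bins must be contiguous and cover the chromosome", what),
           call. = FALSE)
    if (unit01 && (any(tr$value < 0) || any(tr$value > 1)))
      stop(sprintf("%s track values must be in [0, 1]", what), call. = FALSE)
    tr
  }
  hs <- NULL
  if (!is.null(hotspot_intervals)) {
    hs <- as.matrix(as.data.frame(hotspot_intervals)[, 1:2])
    colnames(hs) <- c("start", "end")
    if (nrow(hs) && (any(hs[, 1] < 0) || any(hs[, 2] > physical_length) ||
                     any(hs[, 2] <= hs[, 1])))
      stop("hotspot intervals must be non-empty and within [0, physical_length)",
           call. = FALSE)
  }
  structure(list(name = as.character(name),
                 physical_length = as.numeric(physical_length),
                 map_anchors = ma,
                 hotspot_intervals = hs,
                 gc_track = chk_track(gc_track, "GC", unit01 = TRUE),
                 rt_track = chk_track(rt_track, "RT")),
            class = "chromosome_model")
}

#' Genome model
#'
#' Bundles an ordered set of [chromosome_model()] objects and derives the
#' genome-average recombination rate (total map length in cM divided by total
#' physical length in Mb), the threshold reference for hotspot calling.
#'
#' @param chromosomes list of `chromosome_model` objects with unique names.
#' @return an object of class `genome_model` with elements `chromosomes` and
#'   `genome_average_rate` (cM/Mb).
#' @export
genome_model <- function(chromosomes) {
  if (!length(chromosomes) || !all(vapply(chromosomes, inherits, TRUE,
                                          "chromosome_model")))
    stop("`chromosomes` must be a non-empty list of chromosome_model objects",
         call. = FALSE)
  nm <- vapply(chromosomes, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("chromosome names must be unique", call. = FALSE)
  names(chromosomes) <- nm
  tot_cM <- sum(vapply(chromosomes, function(c) max(c$map_anchors$cM), 0))
  tot_mb <- sum(vapply(chromosomes, `[[`, 0, "physical_length")) / 1e6
  structure(list(chromosomes = chromosomes,
                 genome_average_rate = tot_cM / tot_mb),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosomes, %.1f Mb, %.1f cM (%.3f cM/Mb)\n",
              length(x$chromosomes),
              sum(vapply(x$chromosomes, `[[`, 0, "physical_length")) / 1e6,
              sum(vapply(x$chromosomes, function(c) max(c$map_anchors$cM), 0)),
              x$genome_average_rate))
  for (c in x$chromosomes)
    cat(sprintf("  %-6s %10.0f bp  %8.2f cM  %s hotspot intervals\n",
                c$name, c$physical_length, max(c$map_anchors$cM),
                if (is.null(c$hotspot_intervals)) "?" else nrow(c$hotspot_intervals)))
  invisible(x)
}

#' Genetic length of each chromosome
#'
#' @param genome a `genome_model`.
#' @param units `"cM"` or `"morgans"`.
#' @return named numeric vector of map lengths.
#' @export
genetic_length <- function(genome, units = c("cM", "morgans")) {
  units <- match.arg(units)
  g <- vapply(genome$chromosomes, function(c) max(c$map_anchors$cM), 0)
  if (units == "morgans") g / 100 else g
}

#' Convert between physical and genetic coordinates
#'
#' Monotone piecewise-linear interpolation between the chromosome's map
#' anchors. On cM plateaus (zero-recombination segments) the genetic-to-
#' physical direction is non-unique; the left (smallest bp) endpoint is
#' returned.
#'
#' @param chrom a `chromosome_model`.
#' @param pos numeric vector of positions: bp for `"phys2gen"`, cM for
#'   `"gen2phys"`.
#' @param direction conversion direction.
#' @return numeric vector of converted positions (cM or bp).
#' @export
map_convert <- function(chrom, pos, direction = c("phys2gen", "gen2phys")) {
  direction <- match.arg(direction)
  ma <- chrom$map_anchors
  if (direction == "phys2gen") {
    bad <- pos < 0 | pos > chrom$physical_length
    if (any(bad))
      stop(sprintf("position %g outside [0, %g] bp on %s",
                   pos[which(bad)[1]], chrom$physical_length, chrom$name),
           call. = FALSE)
    stats::approx(ma$bp, ma$cM, xout = pos, ties = "ordered")$y
  } else {
    gmax <- ma$cM[nrow(ma)]
    bad <- pos < 0 | pos > gmax
    if (any(bad))
      stop(sprintf("position %g outside [0, %g] cM on %s",
                   pos[which(bad)[1]], gmax, chrom$name), call. = FALSE)
    # plateaus: duplicated cM values collapsed to their left-most bp
    stats::approx(ma$cM, ma$bp, xout = pos, ties = min)$y
  }
}

#' Call recombination hotspots from the genetic map
#'
#' Scans the chromosome in fixed-width bins and returns the maximal merged
#' intervals whose local recombination rate (cM/Mb across the bin) is at
#' least `fold` times the genome-average rate. The field convention for a
#' hotspot is a local rate of 10 or more times the genomic average.
#'
#' @param chrom a `chromosome_model`.
#' @param genome the `genome_model` providing the genome-average rate.
#' @param fold fold-enrichment threshold (default 10).
#' @param bin_bp scan bin width in bp (default 10 kb).
#' @return two-column matrix of merged `[start, end)` hotspot intervals.
#' @export
hotspot_mask <- function(chrom, genome, fold = 10, bin_bp = 1e4) {
  stopifnot_scalar(fold, "fold", lo = .Machine$double.xmin)
  if (nrow(chrom$map_anchors) < 2L) stop("chromosome has no genetic map", call. = FALSE)
  edges <- unique(c(seq(0, chrom$physical_length, by = bin_bp),
                    chrom$physical_length))
  cm <- map_convert(chrom, edges, "phys2gen")
  rate <- diff(cm) / (diff(edges) / 1e6)         # cM/Mb per bin
  hot <- rate >= fold * genome$genome_average_rate
  if (!any(hot)) return(matrix(numeric(0), 0, 2,
                               dimnames = list(NULL, c("start", "end"))))
  # merge runs of adjacent hot bins
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  cbind(start = edges[starts[keep]], end = edges[ends[keep] + 1L])
}

#' Attach called hotspots to every chromosome
#'
#' Convenience wrapper running [hotspot_mask()] on each chromosome and storing
#' the result in its `hotspot_intervals` field.
#'
#' @inheritParams hotspot_mask
#' @return the updated `genome_model`.
#' @export
call_hotspots <- function(genome, fold = 10, bin_bp = 1e4) {
  genome$chromosomes <- lapply(genome$chromosomes, function(c) {
    c$hotspot_intervals <- hotspot_mask(c, genome, fold = fold, bin_bp = bin_bp)
    c
  })
  genome
}

#' Length-weighted mean of a binned track over an interval
#'
#' @param track data.frame with contiguous `start`, `end`, `value` bins.
#' @param start,end interval bounds (bp, 0-based half-open); vectorized.
#'   Intervals are clipped to the track span; empty (non-positive length
#'   after clipping) intervals are an error.
#' @return numeric vector of length-weighted means.
#' @export
track_mean <- function(track, start, end) {
  if (is.null(track)) stop("track is NULL", call. = FALSE)
  lo <- track$start[1]; hi <- track$end[nrow(track)]
  s <- pmax(start, lo); e <- pmin(end, hi)
  if (any(e <= s)) stop("empty interval after clipping to track span", call. = FALSE)
  # cumulative integral of the step function at bin starts
  cum <- c(0, cumsum(track$value * (track$end - track$start)))
  at <- function(x) {
    i <- findInterval(x, track$start, rightmost.closed = FALSE)
    i <- pmin(pmax(i, 1L), nrow(track))
    cum[i] + track$value[i] * (x - track$start[i])
  }
  (at(e) - at(s)) / (e - s)
}

#' Synthetic genome generator
#'
#' Builds a small configurable genome for simulation studies: chromosomes with
#' given physical and genetic lengths, either a uniform genetic map or a
#' "punctate" map in which a background rate is punctuated by narrow intervals
#' of strongly elevated rate (so that hotspot calling and the hotspot-usage
#' phenotype are exercised), plus randomly generated GC and replication-timing
#' tracks.
#'
#' @param n_chrom number of chromosomes.
#' @param physical_length bp per chromosome (recycled); default a decreasing
#'   ladder from 250 Mb to 50 Mb mimicking the span of human autosomes.
#' @param genetic_length cM per chromosome (recycled); default 1.2 cM/Mb.
#' @param map `"punctate"` (default) or `"uniform"`.
#' @param n_hotspots,hotspot_width,hotspot_fold punctate-map configuration:
#'   count, width (bp) and rate fold-change of elevated-rate intervals per
#'   chromosome.
#' @param track_bin bin width (bp) of the generated GC/RT tracks.
#' @param seed optional seed; the caller's RNG state is preserved.
#' @return a `genome_model` with hotspots called at the default 10-fold
#'   threshold.
#' @export
synthetic_genome <- function(n_chrom = 5,
                             physical_length = NULL,
                             genetic_length = NULL,
                             map = c("punctate", "uniform"),
                             n_hotspots = 12, hotspot_width = 2e3,
                             hotspot_fold = 50, track_bin = 1e5,
                             seed = NULL) {
  map <- match.arg(map)
  if (is.null(physical_length))
    physical_length <- round(seq(2.5e8, 5e7, length.out = n_chrom))
  physical_length <- rep_len(physical_length, n_chrom)
  if (is.null(genetic_length)) genetic_length <- 1.2 * physical_length / 1e6
  genetic_length <- rep_len(genetic_length, n_chrom)
  with_seed(seed, {
    chroms <- lapply(seq_len(n_chrom), function(i) {
      len <- physical_length[i]; gen <- genetic_length[i]
      if (map == "uniform" || n_hotspots == 0) {
        ma <- data.frame(bp = c(0, len), cM = c(0, gen))
      } else {
        hs <- sort(sample.int(len - 3 * hotspot_width, n_hotspots) + hotspot_width)
        hs <- hs[c(TRUE, diff(hs) > 2 * hotspot_width)]   # keep disjoint
        st <- hs; en <- hs + hotspot_width
        hot_bp <- sum(en - st)
        r0 <- gen / (len + (hotspot_fold - 1) * hot_bp)    # background cM/bp
        bp <- c(0, as.vector(rbind(st, en)), len)
        # segments alternate background / hotspot / background ... / background
        rates <- rep(c(r0, r0 * hotspot_fold), length.out = length(bp) - 1)
        ma <- data.frame(bp = bp, cM = c(0, cumsum(rates * diff(bp))))
        ma$cM[nrow(ma)] <- gen                              # exact endpoint
      }
      nb <- ceiling(len / track_bin)
      bs <- (seq_len(nb) - 1) * track_bin
      be <- pmin(bs + track_bin, len)
      gc <- data.frame(start = bs, end = be, value = stats::rbeta(nb, 20, 28))
      rt <- data.frame(start = bs, end = be,
                       value = as.numeric(stats::filter(stats::rnorm(nb), rep(1/3, 3),
                                                        circular = TRUE)))
      chromosome_model(paste0("chr", i), len, ma, gc_track = gc, rt_track = rt)
    })
    call_hotspots(genome_model(chroms))
  })
}
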