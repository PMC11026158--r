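# Small deterministic fixtures shared across test files.

# 100 Mb chromosome with a uniform 150 cM map, constant tracks, one hotspot.
toy_chromosome <- function(name = "chr1", len = 1e8, gen_cM = 150,
                           hotspots = cbind(start = 2e7, end = 3e7),
                           gc = 0.4, rt = 1.5) {
  chromosome_model(
    name, len,
    data.frame(bp = c(0, len), cM = c(0, gen_cM)),
    hotspot_intervals = hotspots,
    gc_track = data.frame(start = 0, end = len, value = gc),
    rt_track = data.frame(start = 0, end = len, value = rt))
}

toy_genome <- function(n = 2, len = c(1e8, 6e7), gen_cM = c(150, 100)) {
  genome_model(lapply(seq_len(n), function(i)
    toy_chromosome(paste0("chr", i), len[i], gen_cM[i],
                   hotspots = cbind(start = 0.2 * len[i], end = 0.3 * len[i]))))
}

# naive reference: per-crossover phenotype computation, straight loops
naive_phenotypes <- function(crossovers, genome, ids, scope) {
  rows <- lapply(ids, function(id) {
    sel <- crossovers$meiosis_id == id
    if (scope != "genome") sel <- sel & crossovers$chrom == scope
    xo <- crossovers[sel, , drop = FALSE]
    if (!nrow(xo))
      return(data.frame(meiosis_id = id, RR = 0L, RH = NA_real_,
                        TD = NA_real_, GC = NA_real_, RT = NA_real_))
    vals <- t(vapply(seq_len(nrow(xo)), function(j) {
      ch <- genome$chromosomes[[xo$chrom[j]]]
      pos <- xo$pos_bp[j]
      len <- ch$physical_length
      hs <- ch$hotspot_intervals
      inhot <- if (is.null(hs) || !nrow(hs)) 0 else
        as.numeric(any(pos >= hs[, 1] & pos < hs[, 2]))
      s <- max(pos - 500, 0); e <- min(pos + 500, len)
      per_base <- function(tr) {
        if (is.null(tr)) return(NA_real_)
        b <- seq(s, e - 1)
        idx <- findInterval(b, tr$start)
        mean(tr$value[idx])
      }
      c(hot = inhot, td = min(pos, len - pos) / len,
        gc = per_base(ch$gc_track), rt = per_base(ch$rt_track))
    }, numeric(4)))
    data.frame(meiosis_id = id, RR = nrow(xo), RH = mean(vals[, "hot"]),
               TD = mean(vals[, "td"]), GC = mean(vals[, "gc"]),
               RT = mean(vals[, "rt"]))
  })
  do.call(rbind, rows)
}
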