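test_that("map conversion interpolates linearly and round-trips", {
  ch <- chromosome_model("chr1", 1e6, data.frame(bp = c(0, 1e6), cM = c(0, 2)))
  expect_equal(map_convert(ch, 5e5, "phys2gen"), 1.0)
  expect_equal(map_convert(ch, 2.0, "gen2phys"), 1e6)
  expect_error(map_convert(ch, 2e6, "phys2gen"), "outside")
  expect_error(map_convert(ch, 3, "gen2phys"), "outside")

  # random anchor sets: round trip within 1 bp / 1e-9 cM
  set.seed(7)
  for (rep in 1:5) {
    bp <- c(0, sort(sample.int(1e6 - 1, 20)), 1e6)
    cm <- c(0, cumsum(runif(21)))
    ch <- chromosome_model("c", 1e6, data.frame(bp = bp, cM = cm))
    x <- runif(1000, 0, 1e6)
    g <- map_convert(ch, x, "phys2gen")
    expect_lt(max(abs(map_convert(ch, g, "gen2phys") - x)), 1)
    y <- runif(200, 0, max(cm))
    b <- map_convert(ch, y, "gen2phys")
    expect_lt(max(abs(map_convert(ch, b, "phys2gen") - y)), 1e-9)
    # monotonicity
    xs <- sort(x)
    expect_true(all(diff(map_convert(ch, xs, "phys2gen")) >= 0))
  }
})

test_that("cM plateaus convert to their left endpoint", {
  ch <- chromosome_model("c", 100, data.frame(bp = c(0, 40, 60, 100),
                                              cM = c(0, 1, 1, 2)))
  expect_equal(map_convert(ch, 1, "gen2phys"), 40)
})

test_that("hotspot calling matches a brute-force bin scan", {
  # 20 equal 1 Mb bins: 19 bins at 1 cM/Mb, one at 30; genome average fixed
  # via a companion chromosome so that the threshold is 24.5
  bp <- seq(0, 2e7, by = 1e6)
  rates <- rep(1, 20); rates[7] <- 30
  ch <- chromosome_model("c1", 2e7, data.frame(bp = bp,
                                               cM = c(0, cumsum(rates))))
  # companion to set genome average: total 49 cM over 20 Mb = 2.45 cM/Mb
  g <- genome_model(list(ch))
  expect_equal(g$genome_average_rate, 2.45)
  hs <- hotspot_mask(ch, g, fold = 10, bin_bp = 1e6)
  expect_equal(nrow(hs), 1L)
  expect_equal(unname(hs[1, ]), c(6e6, 7e6))

  # uniform map: no bin can reach 10x its own average
  chu <- chromosome_model("u", 1e7, data.frame(bp = c(0, 1e7), cM = c(0, 12)))
  gu <- genome_model(list(chu))
  expect_equal(nrow(hotspot_mask(chu, gu, fold = 10)), 0L)

  # random piecewise maps vs exhaustive scan
  set.seed(11)
  for (rep in 1:5) {
    nb <- 15
    bp <- seq(0, nb * 1e5, by = 1e5)
    rates <- rexp(nb, 1)
    ch <- chromosome_model("r", nb * 1e5,
                           data.frame(bp = bp, cM = c(0, cumsum(rates * 0.1))))
    g <- genome_model(list(ch))
    hs <- hotspot_mask(ch, g, fold = 3, bin_bp = 1e5)
    hot_bins <- which(rates >= 3 * g$genome_average_rate)
    covered <- unlist(apply(hs, 1, function(r)
      seq(r[1] / 1e5 + 1, r[2] / 1e5), simplify = FALSE))
    expect_equal(sort(as.numeric(covered)), as.numeric(hot_bins))
  }
})

test_that("hotspot coverage is non-increasing in the fold threshold", {
  set.seed(3)
  g <- synthetic_genome(2, physical_length = 2e7, genetic_length = 40,
                        seed = 5)
  ch <- g$chromosomes[[1]]
  cov <- vapply(c(2, 5, 10, 20), function(f) {
    hs <- hotspot_mask(ch, g, fold = f)
    if (nrow(hs)) sum(hs[, 2] - hs[, 1]) else 0
  }, 0)
  expect_true(all(diff(cov) <= 0))
})

test_that("hotspot calls are invariant under map-anchor refinement", {
  bp <- seq(0, 1e7, by = 1e6)
  rates <- c(1, 1, 25, 1, 1, 1, 30, 1, 1, 1)
  ch <- chromosome_model("c", 1e7, data.frame(bp = bp, cM = c(0, cumsum(rates))))
  g <- genome_model(list(ch))
  # refine: add midpoints of every segment (same piecewise-linear map)
  mids <- bp[-1] - 5e5
  cm_mid <- map_convert(ch, mids, "phys2gen")
  ma2 <- rbind(ch$map_anchors, data.frame(bp = mids, cM = cm_mid))
  ch2 <- chromosome_model("c", 1e7, ma2)
  g2 <- genome_model(list(ch2))
  expect_equal(hotspot_mask(ch, g, fold = 3, bin_bp = 1e6),
               hotspot_mask(ch2, g2, fold = 3, bin_bp = 1e6))
})

test_that("track means are length-weighted and match a per-base oracle", {
  tr <- data.frame(start = c(0, 500), end = c(500, 1000), value = c(0.2, 0.6))
  expect_equal(track_mean(tr, 250, 750), 0.4)
  const <- data.frame(start = 0, end = 1e4, value = 0.4)
  expect_equal(track_mean(const, 123, 9321), 0.4)
  expect_error(track_mean(tr, 700, 700), "empty")

  set.seed(13)
  for (rep in 1:5) {
    edges <- c(0, sort(sample.int(999, 8)), 1000)
    tr <- data.frame(start = edges[-length(edges)], end = edges[-1],
                     value = runif(9))
    s <- sample.int(900, 1); e <- s + sample.int(1000 - s, 1)
    base <- s:(e - 1)
    oracle <- mean(tr$value[findInterval(base, tr$start)])
    expect_equal(track_mean(tr, s, e), oracle, tolerance = 1e-12)
  }
})

test_that("genome constructors validate their invariants", {
  expect_error(chromosome_model("c", 100, data.frame(bp = c(0, 50),
                                                     cM = c(0, 1))),
               "physical_length")
  expect_error(chromosome_model("c", 100, data.frame(bp = c(10, 100),
                                                     cM = c(0, 1))),
               "bp 0")
  expect_error(chromosome_model("c", 100, data.frame(bp = c(0, 50, 100),
                                                     cM = c(0, 2, 1))),
               "non-decreasing")
  ch <- toy_chromosome()
  expect_error(genome_model(list(ch, ch)), "unique")
})
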