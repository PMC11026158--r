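test_that("phenotype arithmetic follows the stated normalizations", {
  g <- toy_genome(1, 1e8, 150)  # hotspot [20, 30) Mb
  xo <- data.frame(meiosis_id = 1, dosage = 0, chrom = "chr1",
                   pos_bp = c(1e7, 9.5e7), pos_cM = c(15, 142))
  ph <- compute_phenotypes(xo, g, per_chromosome = FALSE)
  expect_equal(ph$RR, 2L)
  expect_equal(ph$TD, mean(c(10 / 100, 5 / 100)))
  expect_equal(ph$RH, 0)

  xo2 <- data.frame(meiosis_id = 1, dosage = 0, chrom = "chr1",
                    pos_bp = c(2.5e7, 5e7), pos_cM = c(37, 75))
  expect_equal(compute_phenotypes(xo2, g, per_chromosome = FALSE)$RH, 0.5)

  expect_error(compute_phenotypes(
    data.frame(meiosis_id = 1, dosage = 0, chrom = "chrX", pos_bp = 1,
               pos_cM = 0.1), g), "unknown")
})

test_that("phenotypes match a naive per-crossover reference implementation", {
  set.seed(31)
  g <- synthetic_genome(3, physical_length = c(3e7, 2e7, 1.5e7),
                        genetic_length = c(60, 45, 40), seed = 8)
  spec <- carrier_effect_spec(stahl_params(5, 0.05))
  co <- simulate_recombination_cohort(40, 0.3, spec, g, seed = 32)
  for (scope in c("genome", "chr2")) {
    ph <- compute_phenotypes(co$crossovers, g, meioses = co$meioses)
    ph <- ph[ph$scope == scope, ]
    ref <- naive_phenotypes(co$crossovers, g, co$meioses$meiosis_id, scope)
    expect_equal(ph$RR, ref$RR)
    expect_equal(ph$RH, ref$RH)
    expect_equal(ph$TD, ref$TD)
    expect_equal(ph$GC, ref$GC, tolerance = 1e-3)  # oracle is per-base
    expect_equal(ph$RT, ref$RT, tolerance = 1e-3)
  }
})

test_that("genome-wide crossover count is the sum of per-chromosome counts", {
  g <- toy_genome()
  co <- simulate_recombination_cohort(120, 0.2,
                                      carrier_effect_spec(stahl_params(6, 0.04)),
                                      g, seed = 33)
  ph <- compute_phenotypes(co$crossovers, g, meioses = co$meioses)
  gw <- ph[ph$scope == "genome", ]
  per <- ph[ph$scope != "genome", ]
  sums <- rowsum(per$RR, per$meiosis_id)[as.character(gw$meiosis_id), 1]
  expect_equal(gw$RR, unname(sums))
  # location phenotypes are missing exactly when RR = 0 in scope
  expect_true(all(is.na(per$TD) == (per$RR == 0)))
})

test_that("TD is scale-invariant and centers on 0.25 under a uniform Poisson map", {
  xo <- data.frame(meiosis_id = 1, dosage = 0, chrom = "chr1",
                   pos_bp = c(1e7, 9.5e7), pos_cM = c(15, 142))
  g1 <- toy_genome(1, 1e8, 150)
  g2 <- toy_genome(1, 1e9, 150)  # everything scaled 10x
  xo2 <- transform(xo, pos_bp = pos_bp * 10)
  expect_equal(compute_phenotypes(xo, g1, per_chromosome = FALSE)$TD,
               compute_phenotypes(xo2, g2, per_chromosome = FALSE)$TD)

  g <- toy_genome(1, 1e8, 100)
  co <- simulate_recombination_cohort(4000, 0,
                                      carrier_effect_spec(stahl_params(1, 0)),
                                      g, seed = 34)
  ph <- compute_phenotypes(co$crossovers, g, per_chromosome = FALSE,
                           meioses = co$meioses)
  # E min(U, 1-U) = 1/4 for U uniform; weight by per-meiosis averaging
  td <- ph$TD[!is.na(ph$TD)]
  expect_lt(abs(mean(td) - 0.25), 4 * sd(td) / sqrt(length(td)))
})

test_that("rank-inverse-normal transform matches quantile evaluation", {
  expect_equal(rank_inverse_normal(c(3, 1, 2)),
               qnorm(c(5, 1, 3) / 6), tolerance = 1e-12)
  expect_equal(round(rank_inverse_normal(c(3, 1, 2)), 3),
               c(0.967, -0.967, 0.000))
  expect_equal(rank_inverse_normal(c(5, 5)), c(0, 0))
  x <- c(0.3, NA, 2, 10, 7)
  expect_equal(rank_inverse_normal(x), rank_inverse_normal(exp(x)))
  expect_true(is.na(rank_inverse_normal(x)[2]))
  expect_error(rank_inverse_normal(c(1, NA)), "non-missing")
  set.seed(35)
  z <- rank_inverse_normal(rnorm(5000))
  expect_lt(abs(mean(z)), 1e-10)
  expect_lt(abs(sd(z) - 1), 0.01)
})

test_that("crossover-count filtering partitions the cohort", {
  g <- toy_genome()
  co <- simulate_recombination_cohort(150, 0.2,
                                      carrier_effect_spec(stahl_params(6, 0.04)),
                                      g, seed = 36)
  one <- filter_by_crossover_count(co$meioses, co$crossovers, "chr1",
                                   "exactly_one")
  more <- filter_by_crossover_count(co$meioses, co$crossovers, "chr1",
                                    "more_than_one")
  cnt <- table(factor(co$crossovers$meiosis_id[co$crossovers$chrom == "chr1"],
                      levels = co$meioses$meiosis_id))
  expect_equal(sort(one$meiosis_id), sort(as.integer(names(cnt)[cnt == 1])))
  expect_equal(sort(more$meiosis_id), sort(as.integer(names(cnt)[cnt > 1])))
  expect_equal(nrow(one) + nrow(more) + sum(cnt == 0), nrow(co$meioses))

  toy <- data.frame(meiosis_id = 1:4)
  toyxo <- data.frame(meiosis_id = c(2, 3, 3, 4, 4, 4), chrom = "chr1")
  expect_equal(filter_by_crossover_count(toy, toyxo, "chr1",
                                         "exactly_one")$meiosis_id, 2)
})
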