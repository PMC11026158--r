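test_that("logistic association matches the closed-form 2x2 log odds ratio", {
  status <- rep(c(1, 0), c(100, 100))
  exposed <- c(rep(1, 10), rep(0, 90), rep(1, 5), rep(0, 95))
  a <- logistic_assoc(exposed, status)
  expect_equal(a$beta, log((10 * 95) / (90 * 5)), tolerance = 1e-6)
  expect_equal(a$beta, log(2.111), tolerance = 1e-3)

  # doubling every observation: beta fixed, se shrinks by sqrt(2)
  a2 <- logistic_assoc(rep(exposed, 2), rep(status, 2))
  expect_equal(a2$beta, a$beta, tolerance = 1e-6)
  expect_equal(a2$se, a$se / sqrt(2), tolerance = 1e-4)

  expect_error(logistic_assoc(c(0, 1, 2), c(1, 1, 1)), "both outcome classes")
  # separation
  expect_error(logistic_assoc(rep(c(2, 0), c(30, 30)), rep(c(1, 0), c(30, 30))),
               "separation")
})

test_that("null logistic p-values are uniform", {
  set.seed(61)
  pv <- replicate(300, {
    d <- rbinom(150, 2, 0.3)
    s <- rbinom(150, 1, 0.4)
    tryCatch(logistic_assoc(d, s)$p, error = function(e) NA)
  })
  expect_gt(ks.test(na.omit(pv), "punif")$p.value, 0.01)
})

test_that("inverse-variance pooling reproduces hand computation and identities", {
  m <- ivw_meta(c(0.2, 0.1), c(0.1, 0.2))
  expect_equal(m$beta, 0.18, tolerance = 1e-12)
  expect_equal(m$se, sqrt(1 / 125), tolerance = 1e-12)
  expect_equal(m$or, exp(0.18))
  expect_equal(m$ci_lo, exp(0.18 - 1.96 * m$se))

  # single study: identity, Q = 0
  m1 <- ivw_meta(0.3, 0.15)
  expect_equal(m1$beta, 0.3)
  expect_equal(m1$se, 0.15)
  expect_equal(m1$Q, 0)

  # k identical studies: same beta, se / sqrt(k), Q = 0
  mk <- ivw_meta(rep(0.3, 4), rep(0.15, 4))
  expect_equal(mk$beta, 0.3)
  expect_equal(mk$se, 0.15 / 2)
  expect_equal(mk$Q, 0)

  # order invariance and associativity of pooling
  set.seed(62)
  b <- rnorm(6); s <- runif(6, 0.05, 0.3)
  m_all <- ivw_meta(b, s)
  o <- sample(6)
  expect_equal(ivw_meta(b[o], s[o])$beta, m_all$beta, tolerance = 1e-12)
  mA <- ivw_meta(b[1:3], s[1:3]); mB <- ivw_meta(b[4:6], s[4:6])
  m2 <- ivw_meta(c(mA$beta, mB$beta), c(mA$se, mB$se))
  expect_equal(m2$beta, m_all$beta, tolerance = 1e-12)
  expect_equal(m2$se, m_all$se, tolerance = 1e-12)
})

test_that("pooling agrees with an independent fixed-effects implementation", {
  skip_if_not_installed("metafor")
  set.seed(63)
  b <- rnorm(5, 0.2, 0.1); s <- runif(5, 0.05, 0.2)
  m <- ivw_meta(b, s)
  rf <- metafor::rma(yi = b, sei = s, method = "FE")
  expect_equal(m$beta, as.numeric(rf$beta), tolerance = 1e-8)
  expect_equal(m$se, rf$se, tolerance = 1e-8)
  expect_equal(m$Q, rf$QE, tolerance = 1e-8)
  expect_equal(m$p_het, rf$QEp, tolerance = 1e-8)
})

test_that("class thresholds obey the weighted Bonferroni identity", {
  t1 <- class_thresholds(c(all = 1000), 1)
  expect_equal(t1$threshold, 5e-5)

  t2 <- class_thresholds(c(a = 100, b = 100), c(2, 1))
  expect_equal(t2$threshold[1] / t2$threshold[2], 2)
  expect_equal(sum(t2$n * t2$threshold), 0.05)

  # five classes with weights proportioned like the published threshold
  # ladder (about 330:66:6:3:1)
  w <- c(330, 66, 6, 3, 1)
  n <- c(2e3, 2e4, 3e6, 10e6, 36e6)
  t5 <- class_thresholds(n, w)
  expect_equal(sum(t5$n * t5$threshold), 0.05, tolerance = 1e-12)
  expect_equal(t5$threshold[1] / t5$threshold[5], 330, tolerance = 1e-9)

  set.seed(64)
  for (i in 1:5) {
    k <- sample(2:6, 1)
    n <- sample.int(1e6, k); w <- runif(k, 0.1, 10)
    tt <- class_thresholds(n, w, alpha = 0.05)
    expect_equal(sum(tt$n * tt$threshold), 0.05, tolerance = 1e-12)
  }
  expect_error(class_thresholds(c(0, 10), c(1, 1)), "count")
})

test_that("binomial enrichment matches an exact tail summation", {
  expect_equal(binomial_enrichment(0, 46), 1)
  expect_equal(binomial_enrichment(46, 46), 0.05^46)
  # independent oracle: direct log-pmf summation
  lp <- lchoose(46, 7:46) + (7:46) * log(0.05) + (46 - 7:46) * log(0.95)
  expect_equal(binomial_enrichment(7, 46, 0.05), sum(exp(lp)),
               tolerance = 1e-12)
  expect_lt(binomial_enrichment(7, 46, 0.05), 0.05)
})

test_that("harmonization flips swapped alleles and drops mismatches", {
  ss <- data.frame(chrom = "chr19", pos = 100, ref = c("C", "T", "C", "A"),
                   alt = c("T", "C", "T", "G"),
                   beta = c(0.2, -0.25, 0.21, 0.5),
                   se = 0.1, p = 0.05, af = c(0.01, 0.99, 0.012, 0.3),
                   n_cases = 10, n_controls = 10,
                   cohort = paste0("c", 1:4))
  h <- suppressMessages(harmonize_sumstats(ss))
  expect_equal(nrow(h), 3)               # the A/G row cannot be matched
  expect_equal(h$beta, c(0.2, 0.25, 0.21))
  expect_equal(h$af[2], 0.01)
  expect_true(all(h$ref == "C" & h$alt == "T"))

  mm <- meta_sumstats(h, scheme = class_thresholds(c(missense = 2e4), 1))
  expect_equal(mm$k, 3)
  expect_equal(mm$beta, ivw_meta(h$beta, h$se)$beta)
})

test_that("summary-statistic filters apply MAF and info cutoffs", {
  ss <- data.frame(chrom = "1", pos = 1:4, ref = "A", alt = "G",
                   beta = 0, se = 1, p = 1,
                   af = c(0.5, 0.00005, 0.9999, 0.3),
                   info = c(0.9, 0.9, 0.9, 0.5),
                   n_cases = 1, n_controls = 1, cohort = "c")
  out <- suppressMessages(filter_sumstats(ss))
  expect_equal(out$pos, c(1))
  out2 <- suppressMessages(filter_sumstats(ss[, setdiff(names(ss), "info")]))
  expect_equal(out2$pos, c(1, 4))
})

test_that("meta OR is consistent on simulated multi-cohort data", {
  cc <- simulate_case_control_cohorts(
    n_cases = c(6000, 4000), n_controls = c(24000, 16000),
    allele_freqs = c(0.05, 0.08), true_or = 1.4, seed = 65)
  ss <- do.call(rbind, lapply(split(cc, cc$cohort), function(d) {
    a <- logistic_assoc(d$dosage, d$status)
    data.frame(beta = a$beta, se = a$se)
  }))
  m <- ivw_meta(ss)
  expect_gt(1.4, m$ci_lo)
  expect_lt(1.4, m$ci_hi * 1.1)
  expect_lt(abs(m$or - 1.4), 0.12)
  expect_gt(m$p_het, 0.001)
})
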