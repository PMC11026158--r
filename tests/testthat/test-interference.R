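test_that("gap density reduces to the exponential at nu = 1 and normalizes", {
  expect_equal(interxo_density(0.5, stahl_params(1, 0)), exp(-0.5),
               tolerance = 1e-9)
  for (par in list(c(2, 0), c(6.59, 0.039), c(11.3, 0.2))) {
    sp <- stahl_params(par[1], par[2])
    I <- integrate(function(x) interxo_density(x, sp), 0, Inf,
                   rel.tol = 1e-10)$value
    expect_equal(I, 1, tolerance = 1e-5)
    M <- integrate(function(x) x * interxo_density(x, sp), 0, Inf,
                   rel.tol = 1e-10)$value
    expect_equal(M, 1 / (1 - par[2]), tolerance = 1e-5)
    # survival consistent with the density
    S <- integrate(function(x) interxo_density(x, sp), 0.8, Inf,
                   rel.tol = 1e-10)$value
    expect_equal(interxo_survival(0.8, sp), S, tolerance = 1e-6)
  }
  expect_error(interxo_density(0.5, stahl_params(2, 1)), "Poisson")
})

test_that("Poisson reduction: total log-likelihood is minus the Morgans scored", {
  set.seed(51)
  pos <- replicate(40, sort(runif(rpois(1, 1.8), 0, 1.8)), simplify = FALSE)
  dat <- stahl_data(positions = pos, L = rep(1.8, 40))
  for (p in c(0, 0.25, 0.8)) {
    expect_equal(stahl_loglik(dat, stahl_params(1, p)), -40 * 1.8,
                 tolerance = 1e-8)
  }
  # independence of positions: shuffle positions, same answer
  pos2 <- replicate(40, sort(runif(rpois(1, 1.8), 0, 1.8)), simplify = FALSE)
  dat2 <- stahl_data(positions = pos2, L = rep(1.8, 40))
  expect_equal(stahl_loglik(dat2, stahl_params(1, 0.25)), -40 * 1.8,
               tolerance = 1e-8)
})

test_that("subset-sum likelihood matches brute-force enumeration for n <= 2", {
  # independent naive implementation built on numerical quadrature
  nu <- 3.2; p <- 0.12; L <- 2.5
  K <- 60
  f <- function(x) vapply(x, function(xx)
    sum(2^-(1:K) * dgamma(xx, shape = (1:K) * nu, rate = 2 * nu * (1 - p))), 0)
  Fc <- function(x) integrate(f, 0, x, rel.tol = 1e-12)$value
  h <- function(x) (1 - p) * (1 - Fc(x))
  P0 <- 1 - integrate(Vectorize(h), 0, L, rel.tol = 1e-12)$value

  # n = 0
  d0 <- stahl_data(positions = list(numeric(0)), L = L)
  expect_equal(stahl_loglik(d0, stahl_params(nu, p)),
               log(exp(-p * L) * P0), tolerance = 1e-6)
  # n = 1
  y1 <- 0.9
  d1 <- stahl_data(positions = list(y1), L = L)
  lik1 <- exp(-p * L) * (p * P0 + h(y1) * (1 - Fc(L - y1)))
  expect_equal(stahl_loglik(d1, stahl_params(nu, p)), log(lik1),
               tolerance = 1e-6)
  # n = 2: all four pathway assignments
  y <- c(0.7, 1.9)
  d2 <- stahl_data(positions = list(y), L = L)
  lik2 <- exp(-p * L) * (p^2 * P0 +
    p * h(y[1]) * (1 - Fc(L - y[1])) +
    p * h(y[2]) * (1 - Fc(L - y[2])) +
    h(y[1]) * f(y[2] - y[1]) * (1 - Fc(L - y[2])))
  expect_equal(stahl_loglik(d2, stahl_params(nu, p)), log(lik2),
               tolerance = 1e-6)
})

test_that("empty-interval probability matches simulated empty frequency", {
  set.seed(52)
  for (par in list(c(2, 0.05), c(6.59, 0.039))) {
    sp <- stahl_params(par[1], par[2])
    L <- 1.2
    n <- 2e4
    emp <- mean(lengths(simulate_stahl_process(sp, L, n = n)) == 0)
    d0 <- stahl_data(positions = list(numeric(0)), L = L)
    p0 <- exp(stahl_loglik(d0, sp))
    expect_lt(abs(emp - p0), 3 * sqrt(p0 * (1 - p0) / n))
  }
})

test_that("joint MLE recovers simulation parameters", {
  set.seed(53)
  pos <- list(); Lv <- numeric(0)
  for (l in c(1.5, 2.5)) {
    d <- simulate_stahl_process(stahl_params(2, 0), l, n = 2500)
    pos <- c(pos, d); Lv <- c(Lv, rep(l, 2500))
  }
  dat <- stahl_data(positions = pos, L = Lv)
  fit <- fit_stahl(dat)
  expect_lt(abs(fit$nu - 2) / 2, 0.10)
  expect_true(fit$p >= 0 && fit$p <= 1)
  expect_lt(fit$p, 0.05)  # true p = 0: estimate near the boundary
  # likelihood at the truth cannot beat the MLE
  expect_gte(fit$loglik + 1e-6,
             stahl_loglik(dat, stahl_params(2, 1e-4), method = "grid",
                          grid_n = 2048L))
  expect_true(fit$converged)
})

test_that("profile over fixed p agrees with the joint optimum", {
  set.seed(54)
  d <- simulate_stahl_process(stahl_params(5, 0.08), 2.5, n = 1500)
  dat <- stahl_data(positions = d, L = rep(2.5, 1500))
  fit <- fit_stahl(dat)
  pgrid <- seq(max(fit$p - 0.03, 1e-4), fit$p + 0.03, length.out = 7)
  prof <- vapply(pgrid, function(pp) {
    optimize(function(lnu)
      stahl_loglik(dat, stahl_params(exp(lnu), pp), method = "grid",
                   grid_n = 2048L),
      c(log(1.5), log(20)), maximum = TRUE, tol = 1e-7)$objective
  }, 0)
  expect_lt(max(prof) - fit$loglik, 0.05)
  expect_equal(pgrid[which.max(prof)], fit$p, tolerance = 0.02)
})

test_that("carrier LRT is zero for duplicated groups and detects true differences", {
  set.seed(55)
  d <- simulate_stahl_process(stahl_params(4, 0.05), 2, n = 400)
  dat <- stahl_data(positions = d, L = rep(2, 400))
  lrt <- carrier_lrt(dat, dat)
  expect_lt(lrt$chi2, 0.2)
  expect_gte(lrt$chi2, 0)
  expect_gt(lrt$p_value, 0.5)

  # power: carrier shift at the published effect direction is detected
  dcar <- simulate_stahl_process(stahl_params(2.5, 0.25), 2, n = 700)
  lrt2 <- carrier_lrt(stahl_data(positions = dcar, L = rep(2, 700)), dat)
  expect_lt(lrt2$p_value, 0.01)
})

test_that("larger nu gives lower per-interval count variance", {
  set.seed(56)
  v <- vapply(c(1, 6.59), function(nu)
    var(lengths(simulate_stahl_process(stahl_params(nu, 0.039), 2.2,
                                       n = 6000))), 0)
  expect_lt(v[2], v[1])
})

test_that("stahl_data validates inputs", {
  expect_error(stahl_data(positions = list(c(0.5, 3)), L = 2), "outside")
  expect_error(stahl_data(positions = list(runif(30, 0, 2)), L = 2,
                          max_n = 25), "guard")
})
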