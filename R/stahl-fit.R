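#' Fit the Housworth-Stahl crossover interference model
#'
#' Maximum-likelihood estimation of the interference shape `nu` and escape
#' proportion `p` from crossover genetic positions, using the exact
#' subset-sum likelihood of [stahl_loglik()]. Optimization is performed on
#' the transformed scale `(log nu, logit p)` with a coarse grid of starting
#' values followed by Nelder-Mead refinement; the boundary `p = 0` is handled
#' by flooring `logit p` (the floor corresponds to p of about 6e-6).
#'
#' @param data a [stahl_data()] object, or a crossover data.frame (in which
#'   case `genome` must be given and is forwarded to [stahl_data()]).
#' @param genome optional `genome_model` used when `data` is a data.frame.
#' @param start optional [stahl_params()] (or c(nu, p)) used as a warm start:
#'   a small local grid around it replaces the default coarse grid.
#' @param se compute observed-information standard errors of (nu, p) by
#'   numerical differentiation at the optimum (delta method from the
#'   transformed scale).
#' @param control list overriding optimizer settings: `grid_nu`, `grid_p`
#'   (coarse-grid start values), `maxit`, `reltol` (Nelder-Mead), `method`
#'   (`"grid"` or `"exact"` likelihood evaluation) and `grid_n`
#'   (interpolation-grid resolution).
#' @param ... passed to [stahl_data()] when `data` is a data.frame.
#' @return an object of class `stahl_fit` with elements `nu`, `p`, `loglik`,
#'   `n_meioses`, `n_crossovers`, `converged`, `se` (or NULL) and `data`.
#' @seealso [carrier_lrt()] for the two-group likelihood-ratio test.
#' @export
fit_stahl <- function(data, genome = NULL, start = NULL, se = FALSE,
                      control = list(), ...) {
  if (is.data.frame(data)) data <- stahl_data(data, genome = genome, ...)
  if (!inherits(data, "stahl_data"))
    stop("`data` must be a stahl_data object or a crossover data.frame",
         call. = FALSE)
  ctl <- list(grid_nu = c(1.3, 2.5, 4.5, 8, 14),
              grid_p = c(0.01, 0.04, 0.1, 0.2, 0.35),
              maxit = 300L, reltol = 1e-9,
              method = "grid", grid_n = 2048L,
              logitp_min = -12, logitp_max = 6)
  ctl[names(control)] <- control

  negll <- function(theta) {
    nu <- exp(theta[1L])
    p <- stats::plogis(min(max(theta[2L], ctl$logitp_min), ctl$logitp_max))
    v <- -.stahl_loglik_impl(data, nu, p, method = ctl$method,
                             grid_n = ctl$grid_n)
    if (!is.finite(v)) 1e10 else v
  }

  if (!is.null(start)) {
    if (inherits(start, "stahl_params")) start <- c(start$nu, start$p)
    th0 <- c(log(start[1L]), stats::qlogis(min(max(start[2L], 1e-5), 0.99)))
    grid <- expand.grid(lnu = th0[1L] + c(-0.3, 0, 0.3),
                        lp = th0[2L] + c(-0.7, 0, 0.7))
  } else {
    grid <- expand.grid(lnu = log(ctl$grid_nu), lp = stats::qlogis(ctl$grid_p))
  }
  gvals <- apply(grid, 1L, negll)
  th <- as.numeric(grid[which.min(gvals), ])
  opt <- stats::optim(th, negll, method = "Nelder-Mead",
                      control = list(maxit = ctl$maxit, reltol = ctl$reltol))
  nu_hat <- exp(opt$par[1L])
  p_hat <- stats::plogis(min(max(opt$par[2L], ctl$logitp_min), ctl$logitp_max))
  ses <- NULL
  if (se) {
    H <- try(stats::optimHess(opt$par, negll), silent = TRUE)
    if (!inherits(H, "try-error")) {
      V <- try(solve(H), silent = TRUE)
      if (!inherits(V, "try-error") && all(diag(V) > 0)) {
        # delta method: d nu/d theta1 = nu, d p/d theta2 = p(1-p)
        J <- diag(c(nu_hat, p_hat * (1 - p_hat)))
        Vnat <- J %*% V %*% J
        ses <- sqrt(diag(Vnat))
        names(ses) <- c("nu", "p")
        attr(ses, "vcov") <- structure(Vnat, dimnames = list(c("nu", "p"),
                                                             c("nu", "p")))
      }
    }
  }
  structure(list(nu = nu_hat, p = p_hat,
                 loglik = -opt$value,
                 n_meioses = data$n_meioses,
                 n_crossovers = data$n_crossovers,
                 n_intervals = length(data$positions),
                 converged = opt$convergence == 0L,
                 se = ses, data = data,
                 control = ctl),
            class = "stahl_fit")
}

#' @export
print.stahl_fit <- function(x, ...) {
  cat("Housworth-Stahl interference model fit\n")
  cat(sprintf("  nu (interference) = %.4g%s\n", x$nu,
              if (!is.null(x$se)) sprintf(" (SE %.3g)", x$se["nu"]) else ""))
  cat(sprintf("  p  (escape)       = %.4g%s\n", x$p,
              if (!is.null(x$se)) sprintf(" (SE %.3g)", x$se["p"]) else ""))
  cat(sprintf("  log-likelihood    = %.4f\n", x$loglik))
  cat(sprintf("  data: %d meioses, %d crossovers%s\n", x$n_meioses,
              x$n_crossovers,
              if (x$converged) "" else "  [optimizer did not converge]"))
  invisible(x)
}

#' @export
summary.stahl_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  Morgans scored per meiosis: %.3f (model expects 1 crossover per Morgan)\n",
              sum(object$data$L) / object$n_meioses))
  cat(sprintf("  observed crossovers per meiosis: %.3f\n",
              object$n_crossovers / object$n_meioses))
  invisible(object)
}

#' @export
coef.stahl_fit <- function(object, ...) c(nu = object$nu, p = object$p)

#' @export
logLik.stahl_fit <- function(object, ...) {
  structure(object$loglik, df = 2L, nobs = object$n_meioses, class = "logLik")
}

#' @export
vcov.stahl_fit <- function(object, ...) {
  if (is.null(object$se))
    stop("fit was run with se = FALSE; refit with se = TRUE", call. = FALSE)
  attr(object$se, "vcov")
}

#' Simulate crossover data from a fitted interference model
#'
#' Draws new crossover position sets on the same intervals (chromosome
#' genetic lengths) as the fitted data, at the fitted parameter values.
#'
#' @param object a `stahl_fit`.
#' @param nsim number of replicate datasets.
#' @param seed optional seed (caller's RNG preserved).
#' @param ... unused.
#' @return a list of `nsim` lists of sorted position vectors (Morgans).
#' @export
simulate.stahl_fit <- function(object, nsim = 1, seed = NULL, ...) {
  params <- stahl_params(object$nu, object$p)
  L <- object$data$L
  with_seed(seed, lapply(seq_len(nsim), function(i) {
    lapply(L, function(l) simulate_stahl_process(params, l))
  }))
}

#' Carrier versus noncarrier likelihood-ratio test of interference parameters
#'
#' Tests the null hypothesis that the crossovers of two groups (e.g. carriers
#' and noncarriers of a variant) are governed by the same Housworth-Stahl
#' parameters against the alternative of group-specific parameters, using
#' Wilks' likelihood-ratio statistic `2 (ll_1 + ll_2 - ll_pooled)` referred
#' to a chi-squared distribution with 2 degrees of freedom.
#'
#' Group fits are warm-started from the pooled optimum.
#'
#' @param carrier,noncarrier [stahl_data()] objects (or crossover data.frames
#'   with `genome` supplied) for the two groups.
#' @param genome optional `genome_model` forwarded to [stahl_data()].
#' @param se compute standard errors on the group fits.
#' @param control optimizer control forwarded to [fit_stahl()].
#' @return an object of class `stahl_lrt`: `chi2`, `df`, `p_value`, and the
#'   three `stahl_fit` objects (`fit_carrier`, `fit_noncarrier`, `fit_pooled`).
#' @export
carrier_lrt <- function(carrier, noncarrier, genome = NULL, se = FALSE,
                        control = list()) {
  as_sd <- function(x) if (is.data.frame(x)) stahl_data(x, genome = genome) else x
  carrier <- as_sd(carrier); noncarrier <- as_sd(noncarrier)
  if (!inherits(carrier, "stahl_data") || !inherits(noncarrier, "stahl_data"))
    stop("both groups must be stahl_data objects or crossover data.frames",
         call. = FALSE)
  if (length(carrier$positions) == 0L || length(noncarrier$positions) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  pooled <- stahl_data(positions = c(carrier$positions, noncarrier$positions),
                       L = c(carrier$L, noncarrier$L))
  fit_pool <- fit_stahl(pooled, se = FALSE, control = control)
  st <- stahl_params(fit_pool$nu, fit_pool$p)
  fit_car <- fit_stahl(carrier, start = st, se = se, control = control)
  fit_non <- fit_stahl(noncarrier, start = st, se = se, control = control)
  chi2 <- 2 * (fit_car$loglik + fit_non$loglik - fit_pool$loglik)
  chi2 <- max(chi2, 0)  # numerical floor; the statistic is >= 0 by definition
  structure(list(chi2 = chi2, df = 2L,
                 p_value = stats::pchisq(chi2, df = 2L, lower.tail = FALSE),
                 fit_carrier = fit_car, fit_noncarrier = fit_non,
                 fit_pooled = fit_pool,
                 converged = fit_car$converged && fit_non$converged &&
                   fit_pool$converged),
            class = "stahl_lrt")
}

#' @export
print.stahl_lrt <- function(x, ...) {
  cat("Likelihood-ratio test: shared vs group-specific interference parameters\n")
  cat(sprintf("  carrier:    nu = %.4g, p = %.4g  (ll = %.3f, n = %d)\n",
              x$fit_carrier$nu, x$fit_carrier$p, x$fit_carrier$loglik,
              x$fit_carrier$n_meioses))
  cat(sprintf("  noncarrier: nu = %.4g, p = %.4g  (ll = %.3f, n = %d)\n",
              x$fit_noncarrier$nu, x$fit_noncarrier$p, x$fit_noncarrier$loglik,
              x$fit_noncarrier$n_meioses))
  cat(sprintf("  pooled:     nu = %.4g, p = %.4g  (ll = %.3f)\n",
              x$fit_pooled$nu, x$fit_pooled$p, x$fit_pooled$loglik))
  cat(sprintf("  chi2 = %.4f on %d df, P = %.3g%s\n", x$chi2, x$df, x$p_value,
              if (x$converged) "" else "  [a fit did not converge]"))
  invisible(x)
}
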