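#' Housworth-Stahl model parameters
#'
#' The two-pathway crossover model: an interference pathway in which chiasmata
#' follow a stationary gamma renewal process with shape `nu` and rate
#' `2*nu*(1-p)` per Morgan (each chiasma transmitted to a given product with
#' probability 1/2), plus an interference-free escape pathway contributing
#' crossovers as a Poisson process with rate `p` per Morgan. The combined
#' crossover intensity is exactly 1 per Morgan for every (`nu`, `p`).
#' `nu = 1`, `p = 0` is the homogeneous Poisson (no-interference) special case.
#'
#' @param nu interference shape, > 0. Values above 1 make successive
#'   crossovers more evenly spaced than Poisson.
#' @param p escape proportion in [0, 1].
#' @return an object of class `stahl_params`.
#' @export
stahl_params <- function(nu, p) {
  stopifnot_scalar(nu, "nu", lo = .Machine$double.xmin)
  stopifnot_scalar(p, "p", lo = 0, hi = 1)
  structure(list(nu = nu, p = p), class = "stahl_params")
}

#' @export
print.stahl_params <- function(x, ...) {
  cat(sprintf("Housworth-Stahl parameters: nu = %.4g, p = %.4g\n", x$nu, x$p))
  invisible(x)
}

# Series truncation for the geometric-gamma mixture; 2^-K < 1e-10.
.STAHL_K <- 34L

# log density of the gap between successive interference-pathway crossovers:
# f(x) = sum_{k>=1} 2^-k Gamma(x; shape k*nu, rate 2*nu*(1-p)).
# Vectorized over x.
.stahl_logf <- function(x, nu, p, K = .STAHL_K) {
  rate <- 2 * nu * (1 - p)
  k <- seq_len(K)
  # K x n matrix of log terms
  lt <- matrix(stats::dgamma(rep(x, each = K), shape = k * nu, rate = rate,
                             log = TRUE) - k * log(2),
               nrow = K)
  m <- lt[cbind(max.col(t(lt), ties.method = "first"), seq_along(x))]
  out <- m + log(colSums(exp(sweep(lt, 2L, m))))
  out[!is.finite(m)] <- -Inf
  out
}

# log survival of the inter-crossover gap, 1 - F(x).
# 1 - F = sum_{k<=K} 2^-k * (1 - F_k(x)) + 2^-K (tail components have
# survival ~ 1 at any x of interest since their means grow like k).
.stahl_logS <- function(x, nu, p, K = .STAHL_K) {
  rate <- 2 * nu * (1 - p)
  k <- seq_len(K)
  s <- matrix(stats::pgamma(rep(x, each = K), shape = k * nu, rate = rate,
                            lower.tail = FALSE),
              nrow = K)
  log(colSums(s * 2^-k) + 2^-K)
}

# integral_0^L S(u) du, using int_0^L F_k = L*F_k(L) - (shape/rate)*F_{k+1'}(L)
# where F_{k+1'} is the gamma CDF with shape k*nu + 1.
.stahl_intS <- function(L, nu, p, K = .STAHL_K) {
  rate <- 2 * nu * (1 - p)
  k <- seq_len(K)
  sL <- matrix(stats::pgamma(rep(L, each = K), shape = k * nu, rate = rate,
                             lower.tail = FALSE), nrow = K)
  f1 <- matrix(stats::pgamma(rep(L, each = K), shape = k * nu + 1, rate = rate),
               nrow = K)
  colSums(2^-k * (rep(L, each = K) * sL + (k * nu / rate) * f1)) + 2^-K * L
}

# log probability of observing no interference-pathway crossover on [0, L]
# under the stationary process: P0(L) = 1 - (1-p) * int_0^L S.
.stahl_logP0 <- function(L, nu, p, K = .STAHL_K) {
  v <- 1 - (1 - p) * .stahl_intS(L, nu, p, K)
  log(pmax(v, .Machine$double.xmin))
}

#' Inter-crossover gap density and survival under the Stahl model
#'
#' Density (and survival function) of the genetic distance, in Morgans,
#' between successive crossovers on the interference pathway: a geometric
#' 1/2-thinning of gamma inter-chiasma gaps, i.e. the mixture
#' `sum_k 2^-k Gamma(shape = k*nu, rate = 2*nu*(1-p))`. Its mean is
#' `1/(1-p)` Morgans.
#'
#' @param x non-negative genetic distances (Morgans).
#' @param params a [stahl_params()] object with `p < 1`.
#' @param log return values on the log scale.
#' @return numeric vector of density (or survival) values.
#' @export
interxo_density <- function(x, params, log = FALSE) {
  if (params$p >= 1)
    stop("p = 1 leaves no interference pathway: crossovers are pure Poisson ",
         "with rate 1/Morgan; the gap density is dexp(x)", call. = FALSE)
  if (any(x < 0)) stop("x must be non-negative", call. = FALSE)
  lf <- .stahl_logf(x, params$nu, params$p)
  if (log) lf else exp(lf)
}

#' @rdname interxo_density
#' @export
interxo_survival <- function(x, params, log = FALSE) {
  if (params$p >= 1)
    stop("p = 1 leaves no interference pathway", call. = FALSE)
  if (any(x < 0)) stop("x must be non-negative", call. = FALSE)
  ls <- .stahl_logS(x, params$nu, params$p)
  if (log) ls else exp(ls)
}

#' Assemble crossover data for interference fitting
#'
#' Packs per-(meiosis, chromosome) crossover genetic positions and the
#' chromosome map lengths into the structure consumed by [stahl_loglik()],
#' [fit_stahl()] and [carrier_lrt()]. Meioses with no crossover on a
#' chromosome contribute an empty position vector (they carry likelihood
#' information through the empty-interval probability), so the full meiosis
#' set must be known: it is taken from `meiosis_ids` if given, otherwise from
#' the distinct ids present in `crossovers`.
#'
#' @param crossovers data.frame with columns `meiosis_id`, `chrom`, `pos_cM`
#'   (as written by [simulate_recombination_cohort()] / [read_crossovers()]).
#' @param genome a `genome_model` supplying the chromosomes and their genetic
#'   lengths; crossovers on chromosomes absent from the genome are an error.
#' @param meiosis_ids optional vector of all meiosis ids in the dataset.
#' @param positions,L alternative raw interface: a list of sorted position
#'   vectors (Morgans) and the matching vector of interval lengths (Morgans).
#' @param max_n guard on the per-interval crossover count (the exact
#'   likelihood enumerates `2^n` pathway assignments).
#' @return an object of class `stahl_data`.
#' @export
stahl_data <- function(crossovers = NULL, genome = NULL, meiosis_ids = NULL,
                       positions = NULL, L = NULL, max_n = 25L) {
  if (is.null(positions)) {
    if (is.null(crossovers) || is.null(genome))
      stop("supply either (crossovers, genome) or (positions, L)", call. = FALSE)
    glen <- genetic_length(genome, "morgans")
    bad <- setdiff(unique(crossovers$chrom), names(glen))
    if (length(bad))
      stop("crossovers on chromosome(s) not in the genome: ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (is.null(meiosis_ids)) meiosis_ids <- unique(crossovers$meiosis_id)
    key_m <- rep(factor(meiosis_ids, levels = meiosis_ids),
                 each = length(glen))
    key_c <- rep(names(glen), length(meiosis_ids))
    pos_m <- crossovers$pos_cM / 100
    idx <- match(paste(crossovers$meiosis_id, crossovers$chrom, sep = "\r"),
                 paste(key_m, key_c, sep = "\r"))
    if (anyNA(idx)) stop("crossover rows with unknown meiosis id", call. = FALSE)
    positions <- split(pos_m, factor(idx, levels = seq_along(key_m)))
    positions <- lapply(positions, sort)
    L <- glen[key_c]
    n_meioses <- length(meiosis_ids)
  } else {
    if (is.null(L) || length(L) != length(positions))
      stop("`L` must match `positions` in length", call. = FALSE)
    positions <- lapply(positions, sort)
    n_meioses <- length(positions)
  }
  nn <- lengths(positions)
  if (any(nn > max_n))
    stop(sprintf(paste0("interval with %d crossovers exceeds the subset-sum ",
                        "guard (max_n = %d); audit the input data"),
                 max(nn), max_n), call. = FALSE)
  for (i in which(nn > 0)) {
    y <- positions[[i]]
    if (y[1] < 0 || y[nn[i]] > L[i] + 1e-12)
      stop(sprintf("crossover position outside [0, L] in interval %d", i),
           call. = FALSE)
  }
  structure(list(positions = positions, L = as.numeric(L),
                 n_meioses = n_meioses, n_crossovers = sum(nn),
                 structure = .stahl_finalize(
                   .stahl_structure(positions, as.numeric(L)),
                   as.numeric(L))),
            class = "stahl_data")
}

#' @export
print.stahl_data <- function(x, ...) {
  cat(sprintf("stahl_data: %d meioses, %d intervals, %d crossovers, %.1f Morgans total\n",
              x$n_meioses, length(x$positions), x$n_crossovers, sum(x$L)))
  invisible(x)
}

# Precompute the subset-sum bookkeeping shared by all likelihood evaluations.
# For each interval (meiosis x chromosome) with points y_1 < ... < y_n the
# likelihood is a sum over all 2^n assignments of points to the interference
# pathway; the parameter-independent index structure (which gap / first-point
# / tail value each term uses, and how many points it sends to the escape
# pathway) is built once here.
.stahl_structure <- function(positions, L) {
  R <- length(positions)
  n_by_row <- lengths(positions)
  # memoized subset catalogue per point count n: for every non-empty subset
  # (in mask order) its member indices, first/last member and the per-term
  # layout vectors that only depend on n
  cat_env <- new.env(parent = emptyenv())
  subsets_for <- function(n) {
    key <- as.character(n)
    if (!is.null(cat_env[[key]])) return(cat_env[[key]])
    masks <- seq_len(2L^n - 1L)
    bits <- bitwShiftL(1L, 0:(n - 1L))
    S <- lapply(masks, function(m) which(bitwAnd(m, bits) != 0L))
    sz <- lengths(S)
    first <- vapply(S, `[`, 0L, 1L)
    last <- vapply(S, function(s) s[length(s)], 0L)
    # per-mask consecutive (i, j) gap pairs, flattened, with mask index
    gi <- lapply(seq_along(S), function(k) {
      s <- S[[k]]
      if (length(s) < 2L) return(NULL)
      cbind(mask = k, i = s[-length(s)], j = s[-1L])
    })
    gi <- do.call(rbind, gi)
    out <- list(sz = sz, first = first, last = last, gaps = gi)
    cat_env[[key]] <- out
    out
  }
  acc <- function(n) vector("list", n)
  a_row <- acc(R); a_esc <- acc(R); a_first <- acc(R); a_tail <- acc(R)
  a_gt <- acc(R); a_gv <- acc(R); a_fv <- acc(R)
  hvals <- svals <- vector("list", R)
  term0 <- 0L; f0 <- 0L; h0 <- 0L
  for (r in seq_len(R)) {
    y <- positions[[r]]; n <- n_by_row[r]
    if (n == 0L) {
      a_row[[r]] <- r; a_esc[[r]] <- 0L
      a_first[[r]] <- 0L; a_tail[[r]] <- 0L
      term0 <- term0 + 1L
      next
    }
    hvals[[r]] <- y
    svals[[r]] <- L[r] - y
    if (n > 1L) {
      ij <- which(upper.tri(diag(n)), arr.ind = TRUE)  # column-major: by j then i
      a_fv[[r]] <- y[ij[, 2L]] - y[ij[, 1L]]
    }
    cat <- subsets_for(n)
    n_terms <- 2L^n
    # term order: empty subset first, then masks 1 .. 2^n - 1
    a_row[[r]] <- rep.int(r, n_terms)
    a_esc[[r]] <- c(n, n - cat$sz)
    a_first[[r]] <- c(0L, h0 + cat$first)
    a_tail[[r]] <- c(0L, h0 + cat$last)
    if (!is.null(cat$gaps)) {
      a_gt[[r]] <- term0 + 1L + cat$gaps[, "mask"]
      # gap (i, j), i < j, sits at f0 + (j-1)(j-2)/2 + i (column-major upper tri)
      a_gv[[r]] <- f0 +
        ((cat$gaps[, "j"] - 1L) * (cat$gaps[, "j"] - 2L)) %/% 2L +
        cat$gaps[, "i"]
    }
    term0 <- term0 + n_terms
    h0 <- h0 + n
    f0 <- f0 + (n * (n - 1L)) %/% 2L
  }
  list(fvals = unlist(a_fv, use.names = FALSE),
       hvals = unlist(hvals, use.names = FALSE),
       svals = unlist(svals, use.names = FALSE),
       t_row = unlist(a_row, use.names = FALSE),
       t_esc = unlist(a_esc, use.names = FALSE),
       t_first = unlist(a_first, use.names = FALSE),
       t_tail = unlist(a_tail, use.names = FALSE),
       g_term = unlist(a_gt, use.names = FALSE),
       g_val = unlist(a_gv, use.names = FALSE),
       n_terms = term0, n_rows = R)
}

# parameter-independent lookups reused by every likelihood evaluation
.stahl_finalize <- function(st, L) {
  st$g_rows <- if (length(st$g_term)) unique(st$g_term) else integer(0)
  st$L_unique <- unique(L)
  st$L_idx <- match(L, st$L_unique)
  st
}

# Evaluate log f and log S at arbitrary points, either exactly or through a
# cached interpolation grid (linear interpolation of log f on a log-spaced
# x grid and of log S on a linear grid; exact for nu = 1 where both are
# affine in the grid coordinate).
.stahl_evaluator <- function(nu, p, xmax, method = "exact", grid_n = 512L) {
  if (method == "exact") {
    return(list(logf = function(x) .stahl_logf(x, nu, p),
                logS = function(x) .stahl_logS(x, nu, p)))
  }
  # adaptive series truncation: mixture components whose mass below xmax is
  # negligible add nothing to the density and only the constant 2^-K tail to
  # the survival, so they can be dropped from the grid build
  rate <- 2 * nu * (1 - p)
  mass <- stats::pgamma(xmax * 1.0001, shape = seq_len(.STAHL_K) * nu,
                        rate = rate)
  K <- max(2L, min(which(c(mass, 0) < 1e-13)))
  xg <- exp(seq(log(1e-9), log(xmax * 1.0001), length.out = grid_n))
  lfg <- .stahl_logf(xg, nu, p, K = K)
  xs <- seq(0, xmax * 1.0001, length.out = grid_n)
  lsg <- .stahl_logS(xs, nu, p, K = K)
  list(logf = function(x)
         stats::approx(xg, lfg, xout = pmax(x, 1e-9), rule = 2)$y,
       logS = function(x) stats::approx(xs, lsg, xout = x, rule = 2)$y)
}

#' Exact log-likelihood of crossover data under the Housworth-Stahl model
#'
#' For each scored interval the likelihood sums, over every assignment of the
#' observed crossovers to the interference pathway, the product of an escape
#' term `p^(n-m) exp(-p L)` and a stationary-renewal term: the first assigned
#' point through the forward-recurrence density `h(x) = (1-p) S(x)`, the
#' between-point gaps through the gap density `f`, the final stretch through
#' the survival `S(L - y_last)`, and `P0(L) = 1 - (1-p) int_0^L S` when no
#' point is assigned. With `nu = 1` the model collapses to a unit-rate Poisson
#' process and the total log-likelihood equals minus the total length scored,
#' whatever the crossover positions.
#'
#' @param data a [stahl_data()] object.
#' @param params a [stahl_params()] object.
#' @param method `"exact"` evaluates the gamma-mixture density/survival at
#'   every required point; `"grid"` interpolates them from a cached grid
#'   (used internally by the optimizer for speed).
#' @param grid_n grid resolution for `method = "grid"`.
#' @return the total log-likelihood (a scalar).
#' @export
stahl_loglik <- function(data, params, method = c("exact", "grid"),
                         grid_n = 512L) {
  method <- match.arg(method)
  if (!inherits(data, "stahl_data")) stop("`data` must be a stahl_data object",
                                          call. = FALSE)
  .stahl_loglik_impl(data, params$nu, params$p, method, grid_n)
}

.stahl_loglik_impl <- function(data, nu, p, method = "exact", grid_n = 512L) {
  st <- data$structure
  L <- data$L
  if (p >= 1) {
    # pure Poisson escape pathway at rate p = 1 is the only consistent case
    if (abs(p - 1) > 0) p <- 1
    n <- lengths(data$positions)
    return(sum(n * log(p)) - sum(L) * p)
  }
  ev <- .stahl_evaluator(nu, p, xmax = max(L), method = method, grid_n = grid_n)
  lf <- if (length(st$fvals)) ev$logf(st$fvals) else numeric(0)
  lh <- if (length(st$hvals)) log1p(-p) + ev$logS(st$hvals) else numeric(0)
  ls <- if (length(st$svals)) ev$logS(st$svals) else numeric(0)
  lp0 <- .stahl_logP0(st$L_unique, nu, p)[st$L_idx]
  # per-term gap-log sums
  gs <- numeric(st$n_terms)
  if (length(st$g_term)) {
    rs <- rowsum(lf[st$g_val], st$g_term, reorder = FALSE)
    gs[st$g_rows] <- rs[, 1L]
  }
  empty <- st$t_first == 0L
  tl <- numeric(st$n_terms)
  tl[empty] <- lp0[st$t_row[empty]]
  tl[!empty] <- lh[st$t_first[!empty]] + gs[!empty] + ls[st$t_tail[!empty]]
  esc <- st$t_esc
  if (p > 0) tl <- tl + esc * log(p) else tl[esc > 0L] <- -Inf
  tl <- tl - p * L[st$t_row]
  lik <- rowsum(exp(tl), st$t_row, reorder = FALSE)[, 1L]
  if (any(lik == 0)) {
    # underflow fallback: per-row log-sum-exp
    sp <- split(tl, st$t_row)
    return(sum(vapply(sp, logsumexp, 0)))
  }
  sum(log(lik))
}
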