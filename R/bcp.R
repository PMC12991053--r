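# Barry-Hartigan product-partition changepoint model.
#
# A partition rho of n bins into b blocks (indicator vector U, U[n] == 1
# forced) has marginal weight
#
#   Ip(b) * Iw(W, B, b),
#   Ip(b)       = int_0^p0 p^(b-1) (1-p)^(n-b) dp
#   Iw(W, B, b) = int_0^w0 w^((b-1)/2) (W + w B)^(-(n-1)/2) dw,
#
# where W and B are the within- and between-block sums of squares about the
# grand mean. p is the per-boundary changepoint probability (uniform prior
# on [0, p0]) and w = sigma^2 / (sigma^2 + sigma0^2) the noise-to-signal
# ratio (uniform prior on [0, w0]); the grand mean and variances are
# integrated out analytically. Both integrals are evaluated in log space,
# the w-integral through a regularized incomplete beta function, so that
# long profiles do not under- or overflow.

# ---- integral kernels (log scale) ------------------------------------------

log_p_integral <- function(b, n, p0) {
  lbeta(b, n - b + 1) + pbeta(p0, b, n - b + 1, log.p = TRUE)
}

# log Iw with integrand w^a (W + wB)^(-c); a = (b-1)/2 (+1 when computing
# the posterior expectation of w), c = (n-1)/2. Returns +Inf in the
# divergent W = 0 limit (see .log_odds_parts for how limits are compared).
log_w_integral <- function(W, B, b, n, w0, shift = 0, ztol = 0) {
  a <- (b - 1) / 2 + shift
  cc <- (n - 1) / 2
  if (W <= ztol && B <= ztol) return(0)
  if (B <= ztol) return(-cc * log(W) + (a + 1) * log(w0) - log(a + 1))
  if (W <= ztol) {
    e <- a - cc
    if (e <= -1) return(Inf)
    return(-cc * log(B) + (e + 1) * log(w0) - log(e + 1))
  }
  al <- a + 1
  be <- cc - a - 1
  if (be > 0) {
    u0 <- w0 * B / (W + w0 * B)
    (al - cc) * log(W) - al * log(B) + lbeta(al, be) +
      pbeta(u0, al, be, log.p = TRUE)
  } else {
    # b close to n; smooth integrand, no singularity
    logf <- function(w) a * log(w) - cc * log(W + w * B)
    mx <- max(logf(seq(w0 / 400, w0, length.out = 400)))
    mx + log(stats::integrate(function(w) ifelse(w > 0, exp(logf(w) - mx), 0),
                              0, w0, rel.tol = 1e-10)$value)
  }
}

.zero_tol <- function(tss) 1e-10 * max(tss, 1e-300)

# posterior expectation of w given the partition (shrinkage weight toward
# the grand mean); 0 in degenerate limits where the mass piles up at w = 0
.expected_w <- function(W, B, b, n, w0, ztol, tss) {
  if (tss <= 1e-300) return(0)
  den <- log_w_integral(W, B, b, n, w0, shift = 0, ztol = ztol)
  if (!is.finite(den)) return(0)
  num <- log_w_integral(W, B, b, n, w0, shift = 1, ztol = ztol)
  min(max(exp(num - den), 0), w0)
}

# ---- partition bookkeeping -------------------------------------------------

.check_partition <- function(x, rho) {
  n <- length(x)
  if (length(rho) != n)
    stop("'rho' must have the same length as 'x' (", n, ")", call. = FALSE)
  if (!all(rho %in% c(0L, 1L)))
    stop("'rho' must be a binary changepoint-indicator vector", call. = FALSE)
  if (rho[n] != 1L)
    stop("the final position of 'rho' must be a changepoint (U[n] == 1)",
         call. = FALSE)
  invisible(as.integer(rho))
}

.check_observations <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2L)
    stop("need at least two observations", call. = FALSE)
  if (!all(is.finite(x)))
    stop("all observations must be finite; drop masked/NA bins first",
         call. = FALSE)
  x
}

#' Sufficient statistics of a partition
#'
#' Within- and between-block sums of squares of an observation vector under
#' a changepoint partition. These are the only data summaries the
#' product-partition model needs: `W` measures residual noise around the
#' block means and `B` the spread of the block means about the grand mean;
#' `W + B` equals the total sum of squares.
#'
#' @param x numeric vector of per-bin observations.
#' @param rho binary changepoint-indicator vector of the same length;
#'   `rho[i] == 1` means a block ends at bin `i` (the last position must be
#'   1).
#' @return A list with elements `b` (number of blocks), `W` (within-block
#'   sum of squares) and `B` (between-block sum of squares about the grand
#'   mean).
#' @examples
#' block_statistics(c(1, 1, 5, 5), c(0, 1, 0, 1))
#' @export
block_statistics <- function(x, rho) {
  x <- .check_observations(x)
  rho <- .check_partition(x, rho)
  ends <- which(rho == 1L)
  starts <- c(1L, head(ends, -1L) + 1L)
  gm <- mean(x)
  W <- 0
  B <- 0
  for (k in seq_along(ends)) {
    xs <- x[starts[k]:ends[k]]
    bm <- mean(xs)
    W <- W + sum((xs - bm)^2)
    B <- B + length(xs) * (bm - gm)^2
  }
  list(b = length(ends), W = W, B = B)
}

# log odds comparing the partition weights with U[i] = 1 vs 0, given the
# block statistics under both settings. Degenerate (W = 0) limits: the
# divergent side dominates; when both sides are divergent the setting with
# fewer blocks wins, so the odds vanish.
.log_odds_from_stats <- function(s1, s0, n, p0, w0, tss) {
  lp <- log_p_integral(s1$b, n, p0) - log_p_integral(s0$b, n, p0)
  if (tss <= 1e-300) return(lp)
  ztol <- .zero_tol(tss)
  l1 <- log_w_integral(s1$W, s1$B, s1$b, n, w0, ztol = ztol)
  l0 <- log_w_integral(s0$W, s0$B, s0$b, n, w0, ztol = ztol)
  if (!is.finite(l1) && !is.finite(l0)) return(-Inf)
  if (!is.finite(l1)) return(Inf)
  if (!is.finite(l0)) return(-Inf)
  lp + l1 - l0
}

#' Conditional changepoint odds at one position
#'
#' Odds that position `i` is a changepoint given the data and the states of
#' all other indicators — the quantity the Gibbs sampler draws from. The
#' odds are the ratio of two one-dimensional integrals over the changepoint
#' probability `p` and two over the noise-to-signal ratio `w`, evaluated in
#' log space.
#'
#' For degenerate data (all values identical) the likelihood carries no
#' information and the prior odds are returned. For exactly
#' piecewise-constant data, settings that achieve a zero within-block sum
#' of squares dominate in the limit of the `w` prior, so true boundaries
#' get infinite odds and redundant boundaries odds zero.
#'
#' @inheritParams block_statistics
#' @param i position index in `1..(n-1)`; the final, forced changepoint is
#'   never resampled.
#' @param p0 upper bound of the uniform prior on the per-position
#'   changepoint probability, in (0, 1].
#' @param w0 upper bound of the uniform prior on the noise-to-signal ratio,
#'   in (0, 1].
#' @return Non-negative odds `p_i / (1 - p_i)` (possibly `Inf`).
#' @examples
#' x <- c(0, 0, 0, 0, 10, 10, 10, 10)
#' rho <- c(rep(0, 7), 1)
#' conditional_odds(x, rho, 4) > conditional_odds(x, rho, 2)
#' @export
conditional_odds <- function(x, rho, i, p0 = 0.01, w0 = 0.2) {
  x <- .check_observations(x)
  rho <- .check_partition(x, rho)
  n <- length(x)
  if (i < 1 || i > n - 1)
    stop("'i' must lie in 1..(n-1)", call. = FALSE)
  .check_hyper(p0, w0)
  rho1 <- rho
  rho1[i] <- 1L
  rho0 <- rho
  rho0[i] <- 0L
  s1 <- block_statistics(x, rho1)
  s0 <- block_statistics(x, rho0)
  tss <- sum((x - mean(x))^2)
  exp(.log_odds_from_stats(s1, s0, n, p0, w0, tss))
}

.check_hyper <- function(p0, w0) {
  if (!is.numeric(p0) || length(p0) != 1L || p0 <= 0 || p0 > 1)
    stop("'p0' must be a single value in (0, 1]", call. = FALSE)
  if (!is.numeric(w0) || length(w0) != 1L || w0 <= 0 || w0 > 1)
    stop("'w0' must be a single value in (0, 1]", call. = FALSE)
  invisible(NULL)
}

#' One systematic Gibbs sweep over the changepoint indicators
#'
#' Updates `U[1], ..., U[n-1]` in index order, drawing each indicator from
#' its conditional odds given the current state of all others; the final
#' indicator stays fixed at 1. Draws come from the R random number stream,
#' so results are reproducible with [set.seed()].
#'
#' @inheritParams conditional_odds
#' @return The updated indicator vector.
#' @examples
#' set.seed(1)
#' x <- rep(c(0, 1), each = 10) + rnorm(20, sd = 0.1)
#' rho <- c(rep(0L, 19), 1L)
#' gibbs_sweep(x, rho)
#' @export
gibbs_sweep <- function(x, rho, p0 = 0.01, w0 = 0.2) {
  x <- .check_observations(x)
  rho <- .check_partition(x, rho)
  .check_hyper(p0, w0)
  bcp_sweep_cpp(x, rho, p0, w0)
}

#' Conditional posterior means given a partition
#'
#' The posterior mean of the signal conditional on a partition assigns every
#' bin of a block the same value: the block sample mean shrunk toward the
#' grand mean by the posterior expectation of the noise-to-signal ratio `w`.
#' As `w0` tends to zero the shrinkage vanishes and the values reduce to the
#' block means.
#'
#' @inheritParams conditional_odds
#' @return Numeric vector of per-bin conditional posterior means.
#' @examples
#' conditional_posterior_means(c(1, 1, 9, 9), c(0, 1, 0, 1))
#' @export
conditional_posterior_means <- function(x, rho, p0 = 0.01, w0 = 0.2) {
  x <- .check_observations(x)
  rho <- .check_partition(x, rho)
  .check_hyper(p0, w0)
  n <- length(x)
  st <- block_statistics(x, rho)
  tss <- sum((x - mean(x))^2)
  ew <- .expected_w(st$W, st$B, st$b, n, w0, .zero_tol(tss), tss)
  ends <- which(rho == 1L)
  starts <- c(1L, head(ends, -1L) + 1L)
  out <- numeric(n)
  gm <- mean(x)
  for (k in seq_along(ends)) {
    idx <- starts[k]:ends[k]
    out[idx] <- (1 - ew) * mean(x[idx]) + ew * gm
  }
  out
}

#' Posterior changepoint probabilities by Gibbs sampling
#'
#' Runs the product-partition changepoint sampler: starting from the
#' partition with no interior changepoints, `burnin + mcmc` systematic
#' sweeps are performed and the retained sweeps are summarized into per-bin
#' posterior changepoint probabilities (the fraction of retained partitions
#' in which each boundary is active), the posterior mean of the signal, and
#' pointwise 95% credible bounds (empirical 2.5% and 97.5% quantiles of the
#' conditional-mean draws).
#'
#' @inheritParams conditional_odds
#' @param x numeric vector of per-bin observations (finite, length >= 2).
#' @param burnin number of discarded warm-up sweeps.
#' @param mcmc number of retained sweeps.
#' @param seed optional integer; when supplied, `set.seed(seed)` is called
#'   first so the run is exactly reproducible.
#' @param keep_draws keep the matrix of per-sweep conditional means
#'   (`mcmc` rows, one column per bin)? Needed for the credible bounds;
#'   turn off to save memory when only probabilities are required.
#' @return An object of class `"bcp_fit"`: a list with elements
#'   `posterior_prob`, `posterior_mean`, `ci_lower`, `ci_upper` (all per
#'   bin; the credible bounds are `NA` when `keep_draws = FALSE`),
#'   `n_iterations_used`, the hyperparameters, and (optionally) `draws`.
#' @examples
#' set.seed(42)
#' x <- rep(c(0, 1), each = 20) + rnorm(40, sd = 0.2)
#' fit <- run_bcp(x, p0 = 0.05, burnin = 100, mcmc = 500)
#' which.max(fit$posterior_prob[1:39])
#' @export
run_bcp <- function(x, p0 = 0.01, w0 = 0.2, burnin = 500, mcmc = 2000,
                    seed = NULL, keep_draws = TRUE) {
  x <- .check_observations(x)
  .check_hyper(p0, w0)
  if (burnin < 0 || mcmc < 1)
    stop("'burnin' must be >= 0 and 'mcmc' >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  res <- bcp_mcmc_cpp(x, p0, w0, as.integer(burnin), as.integer(mcmc),
                      keep_draws)
  n <- length(x)
  if (keep_draws) {
    qs <- apply(res$draws, 2, quantile, probs = c(0.025, 0.975),
                names = FALSE, type = 7)
    ci_lower <- qs[1, ]
    ci_upper <- qs[2, ]
  } else {
    ci_lower <- ci_upper <- rep(NA_real_, n)
  }
  out <- list(posterior_prob = res$prob,
              posterior_mean = res$mean,
              ci_lower = ci_lower,
              ci_upper = ci_upper,
              n_iterations_used = as.integer(mcmc),
              burnin = as.integer(burnin),
              p0 = p0, w0 = w0, seed = seed,
              n = n)
  if (keep_draws) out$draws <- res$draws
  class(out) <- "bcp_fit"
  out
}

#' @export
print.bcp_fit <- function(x, ...) {
  cat("Product-partition changepoint fit\n")
  cat(sprintf("  bins: %d, retained sweeps: %d (burnin %d)\n",
              x$n, x$n_iterations_used, x$burnin))
  cat(sprintf("  priors: p0 = %g, w0 = %g\n", x$p0, x$w0))
  ip <- x$posterior_prob[-x$n]
  cat(sprintf("  interior boundaries with p* > 0.5: %d (max p* = %.3f)\n",
              sum(ip > 0.5), max(ip)))
  invisible(x)
}

#' Exact posterior by partition enumeration
#'
#' Enumerates all `2^(n-1)` partitions of a short observation vector,
#' integrates the model weight of each over the `p` and `w` priors by
#' numerical quadrature, and returns exact marginal changepoint
#' probabilities and posterior means. Serves as an independent correctness
#' oracle for the Gibbs sampler; it is only feasible for small `n`.
#'
#' Exactly piecewise-constant data make some partition weights diverge in
#' the `w` prior's lower limit; the enumeration then ranks partitions by
#' their order of divergence, so the posterior concentrates on the coarsest
#' partitions that interpolate the data, mirroring the sampler's limit
#' behavior.
#'
#' @inheritParams run_bcp
#' @param max_n enumeration limit; inputs longer than this raise an error.
#' @return A list with `posterior_prob` and `posterior_mean`, both per bin.
#' @examples
#' exact_posterior(c(0, 0, 5, 5), p0 = 0.2)$posterior_prob
#' @export
exact_posterior <- function(x, p0 = 0.01, w0 = 0.2, max_n = 14L) {
  x <- .check_observations(x)
  .check_hyper(p0, w0)
  n <- length(x)
  if (n > max_n)
    stop("exact enumeration supports at most n = ", max_n, " bins",
         call. = FALSE)
  m <- n - 1L
  tss <- sum((x - mean(x))^2)
  ztol <- .zero_tol(tss)
  cc <- (n - 1) / 2
  npart <- 2L^m
  logw <- numeric(npart)
  order_ <- numeric(npart)   # divergence order in the w lower limit
  probs <- matrix(0L, npart, n)
  means <- matrix(0, npart, n)
  for (k in 0:(npart - 1L)) {
    u <- c(as.integer(intToBits(k))[seq_len(m)], 1L)
    st <- block_statistics(x, u)
    lp <- log_p_integral(st$b, n, p0)
    if (tss <= 1e-300) {
      lw <- lp
      ord <- 0
    } else if (st$W <= ztol && st$b <= n - 2L && st$B > ztol) {
      ord <- (n - st$b - 2) / 2
      lw <- lp - cc * log(st$B) - log(ord)
    } else {
      ord <- 0
      lw <- lp + .log_w_quadrature(st$W, st$B, st$b, n, w0, ztol)
    }
    logw[k + 1L] <- lw
    order_[k + 1L] <- ord
    probs[k + 1L, ] <- u
    ew <- if (ord > 0) 0 else
      .expected_w(st$W, st$B, st$b, n, w0, ztol, tss)
    ends <- which(u == 1L)
    starts <- c(1L, head(ends, -1L) + 1L)
    gm <- mean(x)
    for (j in seq_along(ends)) {
      idx <- starts[j]:ends[j]
      means[k + 1L, idx] <- (1 - ew) * mean(x[idx]) + ew * gm
    }
  }
  keep <- order_ >= max(order_) - 1e-12
  lw <- logw[keep]
  wts <- exp(lw - max(lw))
  wts <- wts / sum(wts)
  list(posterior_prob = colSums(wts * probs[keep, , drop = FALSE]),
       posterior_mean = colSums(wts * means[keep, , drop = FALSE]))
}

# numerical quadrature for the oracle: deliberately a different route than
# the incomplete-beta closed form used by the sampler
.log_w_quadrature <- function(W, B, b, n, w0, ztol) {
  a <- (b - 1) / 2
  cc <- (n - 1) / 2
  if (B <= ztol) return(-cc * log(W) + (a + 1) * log(w0) - log(a + 1))
  if (W <= ztol) {  # convergent tail case b > n - 2
    e <- a - cc
    return(-cc * log(B) + (e + 1) * log(w0) - log(e + 1))
  }
  logf <- function(w) a * log(w) - cc * log(W + w * B)
  mx <- max(logf(seq(w0 / 500, w0, length.out = 500)))
  mx + log(stats::integrate(function(w) ifelse(w > 0, exp(logf(w) - mx), 0),
                            0, w0, rel.tol = 1e-11,
                            subdivisions = 500L)$value)
}
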