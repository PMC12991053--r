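# The product-partition model: sufficient statistics, conditional odds,
# Gibbs sweeps, the full sampler and the exact enumeration oracle.

test_that("block statistics decompose the total sum of squares", {
  s <- block_statistics(c(1, 1, 5, 5), c(0, 1, 0, 1))
  expect_identical(s$b, 2L)
  expect_equal(s$W, 0)
  expect_equal(s$B, 16)

  s <- block_statistics(rep(2, 4), c(1, 0, 0, 1))
  expect_equal(s$W, 0)
  expect_equal(s$B, 0)

  set.seed(1)
  for (rep in 1:10) {
    x <- rnorm(10)
    rho <- c(rbinom(9, 1, 0.4), 1L)
    s <- block_statistics(x, rho)
    tss <- sum((x - mean(x))^2)
    expect_equal(s$W + s$B, tss, tolerance = 1e-9)
    expect_identical(s$b, as.integer(sum(rho)))
  }

  expect_error(block_statistics(1:4, c(0, 1)), "same length")
  expect_error(block_statistics(1:4, c(0, 0, 0, 0)), "final position")
})

test_that("conditional odds favor a real boundary and are symmetric on constant data", {
  x <- c(0, 0, 0, 0, 10, 10, 10, 10)
  rho <- c(rep(0L, 7), 1L)
  at_boundary <- conditional_odds(x, rho, 4, p0 = 0.2)
  interior <- vapply(c(1, 2, 6), function(i)
    conditional_odds(x, rho, i, p0 = 0.2), numeric(1))
  expect_true(all(at_boundary > 1e3 * interior))
  # exact posterior agrees about where the changepoint belongs
  ex <- exact_posterior(x, p0 = 0.2)
  expect_identical(which.max(ex$posterior_prob[1:7]), 4L)

  xc <- rep(3.7, 9)
  odds <- vapply(1:8, function(i)
    conditional_odds(xc, c(rep(0L, 8), 1L), i, p0 = 0.1), numeric(1))
  expect_true(all(abs(odds - odds[1]) < 1e-12))
})

test_that("R and C++ conditional-odds kernels agree", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    x <- rnorm(n)
    rho <- c(rbinom(n - 1, 1, 0.3), 1L)
    i <- sample(seq_len(n - 1), 1)
    lo_r <- log(conditional_odds(x, rho, i, p0 = 0.15, w0 = 0.2))
    lo_c <- bcpseg:::bcp_log_odds_cpp(x, rho, i - 1L, 0.15, 0.2)
    expect_equal(lo_r, lo_c, tolerance = 1e-6)
  }
})

test_that("a Gibbs sweep is deterministic under seeding and respects the prior", {
  x <- step_profile(30, 15, 2, 0.2)
  rho <- c(rep(0L, 29), 1L)
  set.seed(5)
  a <- gibbs_sweep(x, rho)
  set.seed(5)
  b <- gibbs_sweep(x, rho)
  expect_identical(a, b)
  expect_identical(a[30], 1L)

  # constant data with a tiny p0: the all-zero interior survives the sweep
  set.seed(6)
  out <- gibbs_sweep(rep(1, 20), c(rep(0L, 19), 1L), p0 = 1e-4)
  expect_identical(out, c(rep(0L, 19), 1L))

  # long chain on two-level data visits the true boundary most often
  set.seed(7)
  x <- step_profile(40, 20, 1.5, 0.3)
  rho <- c(rep(0L, 39), 1L)
  freq <- numeric(40)
  for (it in 1:400) {
    rho <- gibbs_sweep(x, rho, p0 = 0.05)
    if (it > 100) freq <- freq + rho
  }
  expect_identical(which.max(freq[1:39]), 20L)
})

test_that("conditional posterior means are blockwise constant with shrinkage", {
  m <- conditional_posterior_means(c(1, 1, 9, 9), c(0, 1, 0, 1))
  expect_equal(m[1], m[2])
  expect_equal(m[3], m[4])
  expect_true(m[1] < m[3])
  # shrinkage pulls both levels toward the grand mean 5
  expect_true(m[1] >= 1 && m[3] <= 9)

  # single block: every bin gets the grand mean
  x <- c(2, 4, 1, 7)
  expect_equal(conditional_posterior_means(x, c(0, 0, 0, 1)),
               rep(mean(x), 4))

  # w0 -> 0 limit reduces to the block sample means
  x <- c(1, 1.5, 8, 9)
  m <- conditional_posterior_means(x, c(0, 1, 0, 1), w0 = 1e-9)
  expect_equal(m, c(1.25, 1.25, 8.5, 8.5), tolerance = 1e-5)
})

test_that("sampler matches the exact posterior on small data", {
  set.seed(42)
  for (rep in 1:4) {
    n <- sample(5:8, 1)
    x <- rnorm(n) + rep(c(0, 2), each = ceiling(n / 2))[1:n]
    ex <- exact_posterior(x, p0 = 0.2)
    fit <- run_bcp(x, p0 = 0.2, burnin = 500, mcmc = 20000, seed = 100 + rep,
                   keep_draws = FALSE)
    bound <- pmax(3 * sqrt(ex$posterior_prob * (1 - ex$posterior_prob) /
                             (20000 / 5)), 2e-3)
    expect_true(all(abs(fit$posterior_prob - ex$posterior_prob) < bound))
    # posterior means agree too
    expect_equal(fit$posterior_mean, ex$posterior_mean, tolerance = 0.02)
  }
})

test_that("run_bcp localizes a boundary and is reproducible", {
  set.seed(9)
  x <- step_profile(200, 100, 1, 0.1)
  fit <- run_bcp(x, burnin = 200, mcmc = 600, seed = 31)
  expect_identical(fit$n_iterations_used, 600L)
  imax <- which.max(fit$posterior_prob[1:199])
  expect_true(abs(imax - 100) <= 2)
  # probability bounds and the forced final changepoint
  expect_true(all(fit$posterior_prob >= 0 & fit$posterior_prob <= 1))
  expect_identical(fit$posterior_prob[200], 1)
  expect_true(all(fit$ci_lower <= fit$ci_upper))

  fit2 <- run_bcp(x, burnin = 200, mcmc = 600, seed = 31)
  expect_identical(fit$posterior_prob, fit2$posterior_prob)
  expect_identical(fit$posterior_mean, fit2$posterior_mean)
  expect_identical(fit$ci_lower, fit2$ci_lower)

  expect_error(run_bcp(c(1)), "at least two")
  expect_error(run_bcp(c(1, NA, 2)), "finite")
  expect_error(run_bcp(x, mcmc = 0), "mcmc")
})

test_that("reversing the data reverses the interior posterior", {
  set.seed(13)
  x <- rnorm(7) + c(0, 0, 0, 1.5, 1.5, 1.5, 1.5)
  a <- exact_posterior(x, p0 = 0.2)$posterior_prob
  b <- exact_posterior(rev(x), p0 = 0.2)$posterior_prob
  n <- 7
  # boundary after bin i maps to boundary after bin n - i
  for (i in 1:(n - 1)) expect_equal(a[i], b[n - i], tolerance = 1e-8)
})

test_that("the posterior is invariant to adding a constant", {
  set.seed(14)
  x <- rnorm(8)
  a <- exact_posterior(x, p0 = 0.2)$posterior_prob
  b <- exact_posterior(x + 100, p0 = 0.2)$posterior_prob
  expect_equal(a, b, tolerance = 1e-7)

  x <- step_profile(60, 30, 1, 0.2)
  f1 <- run_bcp(x, burnin = 100, mcmc = 300, seed = 2, keep_draws = FALSE)
  f2 <- run_bcp(x + 5, burnin = 100, mcmc = 300, seed = 2, keep_draws = FALSE)
  expect_equal(f1$posterior_prob, f2$posterior_prob, tolerance = 1e-9)
})

test_that("exact enumeration handles the smallest and degenerate cases", {
  # n = 2: direct two-partition computation
  x <- c(0, 1)
  p0 <- 0.3
  w0 <- 0.2
  ex <- exact_posterior(x, p0 = p0, w0 = w0)
  # weight of u = (1, 1): b = 2, W = 0, B = 0.5; u = (0, 1): b = 1, W = 0.5
  lw2 <- log(integrate(function(p) p * (1 - p)^0, 0, p0)$value) +
    log(integrate(function(w) sqrt(w) * (0.5 * w)^-0.5, 0, w0)$value)
  lw1 <- log(integrate(function(p) (1 - p), 0, p0)$value) +
    log(integrate(function(w) rep(0.5^-0.5, length(w)), 0, w0)$value)
  expect_equal(ex$posterior_prob[1],
               exp(lw2) / (exp(lw2) + exp(lw1)), tolerance = 1e-6)

  # constant data: interior probabilities all equal
  ex <- exact_posterior(rep(2, 6), p0 = 0.2)
  expect_true(all(abs(ex$posterior_prob[1:5] - ex$posterior_prob[1]) < 1e-12))

  expect_error(exact_posterior(rnorm(20)), "at most")
})

test_that("noiseless piecewise-constant data concentrate the posterior on the truth", {
  x <- rep(c(1, 3, 2), times = c(4, 4, 4))
  ex <- exact_posterior(x, p0 = 0.1)
  expect_equal(ex$posterior_prob[c(4, 8)], c(1, 1), tolerance = 1e-9)
  expect_true(all(ex$posterior_prob[c(1:3, 5:7, 9:11)] < 1e-9))
  expect_equal(ex$posterior_mean, x, tolerance = 1e-9)

  set.seed(3)
  fit <- run_bcp(x, burnin = 50, mcmc = 100, keep_draws = FALSE)
  expect_equal(fit$posterior_prob[c(4, 8)], c(1, 1))
  expect_equal(sum(fit$posterior_prob[c(1:3, 5:7, 9:11)]), 0)
  expect_equal(fit$posterior_mean, x)
})
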