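# Posterior probabilities -> segments: filtering, peak calling, median
# reconstruction, merging, and the assembled pipeline.

test_that("probability filtering applies a strict threshold", {
  expect_equal(filter_probabilities(c(0.02, 0.5, 0.04, 0.9), 0.05),
               c(0, 0.5, 0, 0.9))
  # a value exactly at the threshold is dropped (strict inequality)
  expect_equal(filter_probabilities(c(0.05, 0.051), 0.05), c(0, 0.051))
  # relative mode: threshold is a fraction of the largest probability
  expect_equal(filter_probabilities(c(0.08, 0.9, 0.095), 0.1,
                                    relative = TRUE),
               c(0, 0.9, 0.095))
  expect_equal(filter_probabilities(rep(0, 5), 0.05), rep(0, 5))
  expect_error(filter_probabilities(c(0.5), epsilon = 1.5), "epsilon")
  expect_error(filter_probabilities(c(1.2), 0.05), "probabilities")
})

test_that("peak detection finds isolated maxima, plateau centers and respects separation", {
  expect_identical(detect_peaks(c(0, 0, 0.9, 0, 0, 0.8, 0)), c(3L, 6L))
  # plateau of three returns its center
  expect_identical(detect_peaks(c(0, 0.7, 0.7, 0.7, 0)), 3L)
  # even plateau: left of center
  expect_identical(detect_peaks(c(0, 0.7, 0.7, 0)), 2L)
  expect_identical(detect_peaks(rep(0, 6)), integer(0))
  # close peaks: the higher one wins
  expect_identical(detect_peaks(c(0, 0.5, 0, 0.9, 0), min_separation = 3),
                   4L)
  # equal heights, too close: the earlier one wins
  expect_identical(detect_peaks(c(0.6, 0, 0.6, 0, 0), min_separation = 3),
                   1L)
  # adjacent rising-falling structure keeps a single summit
  expect_identical(detect_peaks(c(0.2, 0.5, 0.9, 0.4, 0)), 3L)
})

test_that("noise scale estimation is robust and location invariant", {
  x <- rep(c(0, 4), each = 25)
  expect_equal(estimate_sigma(x, changepoints = 26), 0)

  set.seed(21)
  x <- rnorm(10000, 0, 0.1)
  s <- estimate_sigma(x, integer(0))
  expect_true(abs(s - 0.1) / 0.1 < 0.05)
  expect_equal(estimate_sigma(x + 7, integer(0)), s)

  # all single-bin segments: falls back to the first-difference MAD
  x <- rnorm(50, 0, 0.2)
  s <- estimate_sigma(x, changepoints = 2:50)
  expect_equal(s, mad(diff(x)) / sqrt(2))
  expect_true(s > 0)
})

test_that("median reconstruction tiles the bins and resists outliers", {
  p <- reconstruct_profile(c(1, 1, 1, 5, 5, 5), changepoints = 4)
  expect_equal(p$start, c(1, 4))
  expect_equal(p$end, c(3, 6))
  expect_equal(p$value, c(1, 5))

  p <- reconstruct_profile(c(1, 1, 100, 1))
  expect_equal(nrow(p), 1L)
  expect_equal(p$value, 1)

  expect_equal(reconstruct_profile(c(3, 1, 4))$value, 3)  # median of all

  expect_error(reconstruct_profile(1:10, c(5, 5)), "duplicate")
  expect_error(reconstruct_profile(1:10, c(7, 3)), "sorted")
  expect_error(reconstruct_profile(1:10, 11), "2..n")
  expect_error(reconstruct_profile(1:10, 1), "2..n")
})

test_that("merging removes the smallest sub-threshold gap first and converges", {
  x <- c(rep(1, 10), rep(1.01, 10), rep(5, 10))
  p <- reconstruct_profile(x, c(11, 21))
  m <- merge_segments(p, x, eta = 0.5, sigma = 0.1)
  expect_equal(nrow(m), 2L)
  expect_equal(m$end[1], 20)
  expect_equal(m$value, c(median(x[1:20]), 5))

  # eta = 0 disables merging
  m0 <- merge_segments(p, x, eta = 0, sigma = 0.1)
  expect_equal(nrow(m0), 3L)

  # idempotence and the post-condition on random over-segmented noise
  set.seed(33)
  for (rep in 1:30) {
    x <- rnorm(120, 0, 0.3)
    cps <- sort(sample(2:120, 8))
    p <- reconstruct_profile(x, cps)
    m <- merge_segments(p, x, eta = 0.8)
    sig <- attr(m, "sigma")
    if (nrow(m) > 1)
      expect_true(all(abs(diff(m$value)) >= 0.8 * sig))
    m2 <- merge_segments(m, x, eta = 0.8, sigma = sig)
    expect_equal(as.data.frame(m2), as.data.frame(m))
    # tiling is preserved
    expect_equal(m$start[1], 1)
    expect_equal(m$end[nrow(m)], 120)
    if (nrow(m) > 1)
      expect_true(all(m$start[-1] == m$end[-nrow(m)] + 1))
  }
})

test_that("more aggressive thresholds never create more segments", {
  set.seed(44)
  sim <- simulate_cn_profile(n_bins = 400, purity = 0.25, noise_level = 1,
                             seed = 91)
  fit <- run_bcp(sim$observed, burnin = 200, mcmc = 800, seed = 7,
                 keep_draws = FALSE)
  interior <- fit$posterior_prob[-length(sim$observed)]
  n_peaks <- vapply(c(0.02, 0.05, 0.1, 0.2, 0.5),
                    function(eps) length(detect_peaks(
                      filter_probabilities(interior, eps))),
                    numeric(1))
  expect_true(all(diff(n_peaks) <= 0))

  cps <- detect_peaks(filter_probabilities(interior, 0.05)) + 1L
  p <- reconstruct_profile(sim$observed, cps)
  n_segs <- vapply(c(0, 0.25, 0.5, 1, 2),
                   function(eta) nrow(merge_segments(p, sim$observed,
                                                     eta = eta)),
                   numeric(1))
  expect_true(all(diff(n_segs) <= 0))
})

test_that("noiseless profiles are recovered exactly and constants stay whole", {
  sim <- simulate_cn_profile(n_bins = 300, purity = 0.3, noise_level = 1,
                             base_noise_sd = 0, seed = 15)
  fit <- bcpseg(sim$observed, burnin = 100, mcmc = 300, seed = 1)
  expect_identical(fit$changepoints, sim$changepoints)
  # segment values equal the true mixed levels
  expect_equal(fitted(fit), sim$mixed, tolerance = 1e-12)

  fit <- bcpseg(rep(2, 80), burnin = 50, mcmc = 150, seed = 2)
  expect_equal(nrow(fit$segments), 1L)
  expect_identical(fit$changepoints, integer(0))
})

test_that("multi-chromosome profiles are segmented independently with NA masking", {
  set.seed(55)
  v1 <- c(rep(2, 40), rep(2.8, 40)) + rnorm(80, 0, 0.1)
  v2 <- rep(2, 50) + rnorm(50, 0, 0.1)
  bins <- toy_bins(v1, v2)
  bins$value[c(10, 60)] <- NA  # masked bins
  fit <- bcpseg(bins, burnin = 150, mcmc = 400, seed = 3)

  expect_true(all(is.na(fit$posterior_prob[c(10, 60)])))
  expect_false(anyNA(fit$posterior_prob[-c(10, 60)]))
  # segments tile the usable bins of each chromosome exactly once
  for (ch in c("chr1", "chr2")) {
    segs <- fit$segments[fit$segments$chrom == ch, ]
    expect_equal(segs$start[1], 1)
    n_usable <- sum(bins$chrom == ch & !is.na(bins$value))
    expect_equal(segs$end[nrow(segs)], n_usable)
    expect_equal(sum(segs$n_bins), n_usable)
  }
  # the chr1 boundary is found near bin 41 of the retained index
  chr1 <- fit$segments[fit$segments$chrom == "chr1", ]
  expect_equal(nrow(chr1), 2L)
  expect_true(abs(chr1$start[2] - 40) <= 3)
  # chr2 is constant
  expect_equal(sum(fit$segments$chrom == "chr2"), 1L)

  # fitted/residuals align with the input bins
  expect_equal(length(fitted(fit)), nrow(bins))
  r <- residuals(fit)
  expect_true(all(is.na(r[c(10, 60)])))
  expect_true(max(abs(r), na.rm = TRUE) < 1)
  expect_equal(coef(fit), fit$segments$value)
})
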