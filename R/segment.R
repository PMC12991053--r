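# Posterior probabilities -> segmented profile: filter, peak detection,
# median reconstruction, merge correction.

#' Filter posterior changepoint probabilities
#'
#' Sets probabilities at or below a noise floor `epsilon` to zero, keeping
#' larger values unchanged (strict inequality: a value exactly equal to
#' `epsilon` is dropped). In relative mode the floor adapts to the sample:
#' `epsilon` is interpreted as a fraction of the largest probability in the
#' track, e.g. 0.1 for "10% of the largest posterior changepoint
#' probability".
#'
#' @param p_star numeric vector of posterior changepoint probabilities in
#'   \[0, 1\].
#' @param epsilon noise floor in \[0, 1\] (or the fraction of the maximum in
#'   relative mode).
#' @param relative interpret `epsilon` as a fraction of `max(p_star)`?
#' @return Filtered probability vector of the same length.
#' @examples
#' filter_probabilities(c(0.02, 0.5, 0.04, 0.9), epsilon = 0.05)
#' @export
filter_probabilities <- function(p_star, epsilon = 0.05, relative = FALSE) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L ||
      epsilon < 0 || epsilon > 1)
    stop("'epsilon' must be a single value in [0, 1]", call. = FALSE)
  if (any(p_star < 0 | p_star > 1, na.rm = TRUE))
    stop("'p_star' must contain probabilities in [0, 1]", call. = FALSE)
  eps <- if (relative) epsilon * max(p_star, 0) else epsilon
  ifelse(p_star > eps, p_star, 0)
}

#' Detect peaks in a filtered probability track
#'
#' Local maxima of the filtered posterior changepoint probabilities mark the
#' called changepoints. A position qualifies when its value is positive and
#' not smaller than both neighbors; a plateau of equal positive values
#' that stands above its flanks yields its center position (the
#' left-of-center bin on even-length plateaus). When two peaks lie closer
#' than `min_separation` bins, only the higher one (the earlier one on
#' ties) is kept.
#'
#' @param filtered numeric vector, typically the output of
#'   [filter_probabilities()].
#' @param min_separation minimal distance in bins between reported peaks.
#' @return Sorted integer positions of the peaks (1-based indices into
#'   `filtered`); an empty vector when the track is all zero.
#' @examples
#' detect_peaks(c(0, 0, 0.9, 0, 0, 0.8, 0))
#' detect_peaks(c(0, 0.7, 0.7, 0.7, 0))
#' @export
detect_peaks <- function(filtered, min_separation = 1L) {
  n <- length(filtered)
  if (n == 0L || all(filtered <= 0)) return(integer(0))
  if (min_separation < 1L)
    stop("'min_separation' must be a positive integer", call. = FALSE)
  # collapse into runs of equal value, compare run levels to their flanks
  r <- rle(filtered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  left <- c(-Inf, r$values[-k])
  right <- c(r$values[-1L], -Inf)
  is_peak <- r$values > 0 & r$values >= left & r$values >= right
  # plateau center, left of center when the plateau has even length
  centers <- starts + (r$lengths - 1L) %/% 2L
  peaks <- centers[is_peak]
  heights <- r$values[is_peak]
  if (min_separation > 1L && length(peaks) > 1L) {
    ord <- order(-heights, peaks)   # higher first, earlier on ties
    kept <- integer(0)
    for (i in ord) {
      if (all(abs(peaks[i] - kept) >= min_separation))
        kept <- c(kept, peaks[i])
    }
    peaks <- sort(kept)
  }
  as.integer(peaks)
}

#' Robust noise-scale estimate from within-segment residuals
#'
#' Median absolute deviation (scaled for consistency with a Gaussian
#' standard deviation) of the observations after subtracting their segment
#' medians. When every segment contains a single bin the residuals are
#' identically zero by construction; the estimate then falls back to the
#' MAD of the first differences divided by `sqrt(2)`.
#'
#' @param x numeric vector of per-bin observations.
#' @param changepoints sorted first-bin indices of segments after the
#'   first (1-based, each in `2..n`); empty for a single segment.
#' @return Non-negative noise-scale estimate.
#' @examples
#' estimate_sigma(rep(c(0, 4), each = 25), changepoints = 26)
#' @export
estimate_sigma <- function(x, changepoints = integer(0)) {
  n <- length(x)
  segs <- reconstruct_profile(x, changepoints)
  if (all(segs$n_bins == 1L))
    return(mad(diff(x)) / sqrt(2))
  fit <- rep(segs$value, segs$n_bins)
  mad(x - fit)
}

#' Reconstruct a segmented profile from changepoints
#'
#' Splits the observation vector at the given changepoints and assigns each
#' segment the median of its bins — the median rather than the mean, so a
#' single outlying bin does not displace the segment level.
#'
#' @inheritParams estimate_sigma
#' @return A data frame of class `"segmented_profile"` with one row per
#'   segment and columns `start`, `end` (1-based inclusive bin indices),
#'   `n_bins` and `value` (the segment median).
#' @examples
#' reconstruct_profile(c(1, 1, 1, 5, 5, 5), changepoints = 4)
#' @export
reconstruct_profile <- function(x, changepoints = integer(0)) {
  n <- length(x)
  cps <- as.integer(changepoints)
  if (anyDuplicated(cps))
    stop("duplicate changepoints", call. = FALSE)
  if (is.unsorted(cps))
    stop("'changepoints' must be sorted", call. = FALSE)
  if (length(cps) && (min(cps) < 2L || max(cps) > n))
    stop("changepoints must be first-bin indices in 2..n", call. = FALSE)
  starts <- c(1L, cps)
  ends <- c(cps - 1L, n)
  out <- data.frame(start = starts, end = ends,
                    n_bins = ends - starts + 1L,
                    value = vapply(seq_along(starts), function(k)
                      median(x[starts[k]:ends[k]]), numeric(1)))
  class(out) <- c("segmented_profile", "data.frame")
  out
}

#' Merge segments separated by too small a median shift
#'
#' Undoes changepoints whose adjacent segment medians differ by less than
#' `eta` noise standard deviations: the closest adjacent pair (in SD units)
#' is merged first, the merged segment's median is recomputed from the
#' data, and the procedure repeats until every remaining adjacent pair
#' differs by at least `eta * sigma`. The noise scale is estimated once
#' from the initial segmentation (see [estimate_sigma()]) and held fixed
#' while merging.
#'
#' @param profile a `"segmented_profile"` as returned by
#'   [reconstruct_profile()].
#' @param x the observation vector the profile was built from.
#' @param eta merge threshold in units of the noise standard deviation;
#'   `eta = 0` disables merging.
#' @param sigma optional noise scale; estimated from `profile` when `NULL`.
#' @return The merged `"segmented_profile"`, with the retained noise scale
#'   in attribute `"sigma"`.
#' @examples
#' x <- c(rep(1, 10), rep(1.01, 10), rep(5, 10))
#' p <- reconstruct_profile(x, c(11, 21))
#' merge_segments(p, x, eta = 0.5, sigma = 0.1)
#' @export
merge_segments <- function(profile, x, eta = 0.5, sigma = NULL) {
  if (eta < 0) stop("'eta' must be non-negative", call. = FALSE)
  segs <- as.data.frame(profile)
  if (is.null(sigma))
    sigma <- estimate_sigma(x, segs$start[-1L])
  threshold <- eta * sigma
  repeat {
    if (nrow(segs) < 2L) break
    gaps <- abs(diff(segs$value))
    k <- which.min(gaps)            # smallest gap first; ties -> leftmost
    if (gaps[k] >= threshold) break
    idx <- segs$start[k]:segs$end[k + 1L]
    segs$end[k] <- segs$end[k + 1L]
    segs$n_bins[k] <- length(idx)
    segs$value[k] <- median(x[idx])
    segs <- segs[-(k + 1L), , drop = FALSE]
  }
  rownames(segs) <- NULL
  class(segs) <- c("segmented_profile", "data.frame")
  attr(segs, "sigma") <- sigma
  segs
}

# full pipeline on one plain numeric vector
.segment_vector <- function(x, p0, w0, burnin, mcmc, epsilon, relative,
                            eta, min_separation, keep_draws) {
  n <- length(x)
  fit <- run_bcp(x, p0 = p0, w0 = w0, burnin = burnin, mcmc = mcmc,
                 keep_draws = keep_draws)
  interior <- fit$posterior_prob[-n]   # final boundary is forced, not a CNA
  filtered <- filter_probabilities(interior, epsilon, relative)
  peaks <- detect_peaks(filtered, min_separation)
  cps <- peaks + 1L                    # boundary after bin i -> segment starts at i+1
  segs <- reconstruct_profile(x, cps)
  segs <- merge_segments(segs, x, eta = eta)
  list(fit = fit, filtered = filtered, segments = segs,
       changepoints = segs$start[-1L], sigma = attr(segs, "sigma"))
}

#' Segment a binned copy-number profile
#'
#' The full estimation pipeline: posterior changepoint probabilities by
#' Gibbs sampling ([run_bcp()]), probability filtering
#' ([filter_probabilities()]), peak detection ([detect_peaks()]), median
#' reconstruction ([reconstruct_profile()]) and merging of segments with
#' too small a median shift ([merge_segments()]). Accepts a plain numeric
#' vector or a binned genomic profile from [read_bins()]; chromosomes are
#' segmented independently and bins with missing values are dropped before
#' sampling (results are indexed on the retained bins).
#'
#' @param x numeric vector of per-bin values (e.g. GC-corrected log2
#'   read-depth ratios), or a `"binned_profile"` data frame from
#'   [read_bins()].
#' @param p0 upper bound of the uniform prior on the per-boundary
#'   changepoint probability. Smaller values favor precision (fewer called
#'   boundaries); larger values favor recall in noisy samples.
#' @param w0 upper bound of the uniform prior on the noise-to-signal ratio.
#' @param burnin,mcmc discarded and retained Gibbs sweeps.
#' @param epsilon posterior-probability noise floor; see
#'   [filter_probabilities()].
#' @param relative_epsilon interpret `epsilon` as a fraction of the largest
#'   posterior changepoint probability?
#' @param eta merge threshold in noise-SD units; see [merge_segments()].
#' @param min_separation minimal peak distance in bins.
#' @param seed optional integer seed for exact reproducibility.
#' @param keep_draws keep per-sweep conditional-mean draws (needed for the
#'   95% credible band in `plot`)?
#' @return An object of class `"bcpseg"` with components `segments` (one
#'   row per segment: `chrom` when genomic input, `start`, `end`, `n_bins`,
#'   `value`), `changepoints`, `posterior_prob`, `posterior_mean`,
#'   `ci_lower`, `ci_upper` (aligned to the input bins, `NA` on masked
#'   bins), `sigma` (per-chromosome noise scale), `fits` (per-chromosome
#'   [run_bcp()] results) and the resolved parameters. Methods: `print`,
#'   `summary`, `plot`, `fitted`, `residuals`, `coef`.
#' @examples
#' set.seed(7)
#' x <- rep(c(2, 2.4, 2), each = 40) * (1 + rnorm(120, sd = 0.05))
#' fit <- bcpseg(x, burnin = 100, mcmc = 500)
#' fit$changepoints
#' @export
bcpseg <- function(x, p0 = 0.01, w0 = 0.2, burnin = 500, mcmc = 2000,
                   epsilon = 0.05, relative_epsilon = FALSE, eta = 0.5,
                   min_separation = 1L, seed = NULL, keep_draws = TRUE) {
  cl <- match.call()
  if (!is.null(seed)) set.seed(seed)
  params <- list(p0 = p0, w0 = w0, burnin = burnin, mcmc = mcmc,
                 epsilon = epsilon, relative_epsilon = relative_epsilon,
                 eta = eta, min_separation = min_separation, seed = seed)

  if (inherits(x, "binned_profile")) {
    bins <- x
    chroms <- unique(bins$chrom)
    nbin <- nrow(bins)
    prob <- pmean <- cil <- ciu <- rep(NA_real_, nbin)
    seg_list <- list()
    fits <- list()
    sigma <- numeric(0)
    cps_global <- integer(0)
    for (ch in chroms) {
      sel <- which(bins$chrom == ch)
      usable <- sel[!is.na(bins$value[sel])]
      if (length(usable) < 2L) next
      xs <- bins$value[usable]
      res <- .segment_vector(xs, p0, w0, burnin, mcmc, epsilon,
                             relative_epsilon, eta, min_separation,
                             keep_draws)
      prob[usable] <- res$fit$posterior_prob
      pmean[usable] <- res$fit$posterior_mean
      cil[usable] <- res$fit$ci_lower
      ciu[usable] <- res$fit$ci_upper
      segs <- res$segments
      seg_list[[ch]] <- data.frame(
        chrom = ch,
        start = segs$start, end = segs$end, n_bins = segs$n_bins,
        value = segs$value,
        genomic_start = bins$start[usable[segs$start]],
        genomic_end = bins$end[usable[segs$end]])
      fits[[ch]] <- res$fit
      sigma[ch] <- res$sigma
      cps_global <- c(cps_global, usable[res$changepoints])
    }
    segments <- do.call(rbind, seg_list)
    rownames(segments) <- NULL
    out <- list(segments = segments, changepoints = cps_global,
                posterior_prob = prob, posterior_mean = pmean,
                ci_lower = cil, ci_upper = ciu, sigma = sigma,
                fits = fits, bins = bins, params = params, call = cl)
  } else {
    xs <- .check_observations(x)
    res <- .segment_vector(xs, p0, w0, burnin, mcmc, epsilon,
                           relative_epsilon, eta, min_separation,
                           keep_draws)
    out <- list(segments = res$segments, changepoints = res$changepoints,
                posterior_prob = res$fit$posterior_prob,
                posterior_mean = res$fit$posterior_mean,
                ci_lower = res$fit$ci_lower, ci_upper = res$fit$ci_upper,
                sigma = res$sigma, fits = list(res$fit), data = xs,
                params = params, call = cl)
  }
  class(out) <- "bcpseg"
  out
}
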