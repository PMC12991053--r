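# Synthetic evaluation data: piecewise-constant integer copy-number
# profiles, diluted by tumor purity toward the diploid level 2 and
# corrupted by multiplicative copy-number-dependent Gaussian noise.

#' Simulate a piecewise-constant copy-number state sequence
#'
#' Segment lengths are drawn uniformly from `length_min..length_max` bins
#' and each segment receives an independent copy-number state from
#' `state_values` with probabilities `state_probs`; the last segment is
#' truncated at `n_bins`. Adjacent segments that happen to draw the same
#' state form one constant stretch, so the reported changepoints are the
#' positions where the state actually changes — every true changepoint is
#' detectable in principle.
#'
#' @param n_bins number of genomic bins.
#' @param length_min,length_max segment length bounds in bins.
#' @param state_values integer copy-number states.
#' @param state_probs state probabilities (must sum to 1).
#' @return A list with `cn_state` (integer per bin) and `changepoints`
#'   (sorted 1-based first-bin indices of the state changes).
#' @examples
#' set.seed(1)
#' sim <- simulate_states(200)
#' table(sim$cn_state)
#' @export
simulate_states <- function(n_bins = 1000, length_min = 30, length_max = 50,
                            state_values = 1:5,
                            state_probs = c(0.09, 0.5, 0.27, 0.09, 0.05)) {
  if (length(state_values) != length(state_probs))
    stop("'state_values' and 'state_probs' must have equal length",
         call. = FALSE)
  if (abs(sum(state_probs) - 1) > 1e-9)
    stop("'state_probs' must sum to 1", call. = FALSE)
  if (length_min < 1 || length_min > length_max || length_max > n_bins)
    stop("need 1 <= length_min <= length_max <= n_bins", call. = FALSE)
  cn <- integer(0)
  while (length(cn) < n_bins) {
    len <- sample.int(length_max - length_min + 1L, 1L) + length_min - 1L
    state <- sample(state_values, 1L, prob = state_probs)
    cn <- c(cn, rep(state, len))
  }
  cn <- cn[seq_len(n_bins)]
  list(cn_state = cn,
       changepoints = which(diff(cn) != 0) + 1L)
}

#' Dilute a copy-number signal by tumor purity
#'
#' Mixes the tumor copy-number states with the diploid level 2 contributed
#' by contaminating healthy DNA: `mixed = purity * cn + (1 - purity) * 2`.
#' The neutral state 2 is invariant under dilution.
#'
#' @param cn_state numeric/integer vector of copy-number states.
#' @param purity tumor fraction in (0, 1].
#' @return Numeric vector of mixed signal values.
#' @examples
#' apply_purity(c(1, 2, 3), purity = 0.1)
#' @export
apply_purity <- function(cn_state, purity) {
  if (!is.numeric(purity) || length(purity) != 1L ||
      purity <= 0 || purity > 1)
    stop("'purity' must be a single value in (0, 1]", call. = FALSE)
  purity * cn_state + (1 - purity) * 2
}

#' Add multiplicative copy-number-dependent Gaussian noise
#'
#' `observed[i] = mixed[i] * (1 + e[i])` with independent
#' `e[i] ~ N(0, (noise_level * base_noise_sd)^2)`, so each bin's standard
#' deviation is proportional to its mixed copy number: higher copy numbers
#' carry more noise, and doubling `noise_level` doubles the residual SD.
#' Noise level 1 is the calibration baseline (roughly a normally noisy
#' sample); levels 0.5, 2 and 4 emulate higher and lower sequencing depth.
#'
#' @param mixed numeric vector of purity-diluted signal values.
#' @param noise_level multiplier of the baseline relative noise.
#' @param base_noise_sd relative noise SD per unit of signal at noise
#'   level 1.
#' @return Numeric vector of noisy observations.
#' @examples
#' set.seed(1)
#' add_noise(rep(2, 5), noise_level = 1)
#' @export
add_noise <- function(mixed, noise_level = 1, base_noise_sd = 0.05) {
  if (noise_level < 0 || base_noise_sd < 0)
    stop("noise parameters must be non-negative", call. = FALSE)
  mixed * (1 + rnorm(length(mixed), 0, noise_level * base_noise_sd))
}

#' Simulate one synthetic copy-number sample
#'
#' Draws a piecewise-constant state profile ([simulate_states()]), dilutes
#' it by `purity` ([apply_purity()]) and adds multiplicative noise
#' ([add_noise()]).
#'
#' @inheritParams simulate_states
#' @inheritParams apply_purity
#' @inheritParams add_noise
#' @param seed optional integer seed for exact reproducibility.
#' @return An object of class `"cn_sim"`: a list with `cn_state`,
#'   `changepoints`, `mixed` (noise-free diluted signal), `observed`, and
#'   the generating parameters.
#' @examples
#' sim <- simulate_cn_profile(purity = 0.3, noise_level = 1, seed = 1)
#' length(sim$changepoints)
#' @export
simulate_cn_profile <- function(n_bins = 1000, purity = 0.3, noise_level = 1,
                                base_noise_sd = 0.05, length_min = 30,
                                length_max = 50, state_values = 1:5,
                                state_probs = c(0.09, 0.5, 0.27, 0.09, 0.05),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  st <- simulate_states(n_bins, length_min, length_max, state_values,
                        state_probs)
  mixed <- apply_purity(st$cn_state, purity)
  observed <- add_noise(mixed, noise_level, base_noise_sd)
  out <- list(cn_state = st$cn_state, changepoints = st$changepoints,
              mixed = mixed, observed = observed,
              purity = purity, noise_level = noise_level,
              base_noise_sd = base_noise_sd, n_bins = n_bins, seed = seed)
  class(out) <- "cn_sim"
  out
}

#' @export
print.cn_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic copy-number sample: %d bins, purity %.2f, noise level %g\n",
    x$n_bins, x$purity, x$noise_level))
  cat(sprintf("  %d true changepoints, states %s\n",
              length(x$changepoints),
              paste(sort(unique(x$cn_state)), collapse = ",")))
  invisible(x)
}

#' Simulate a grid of evaluation samples
#'
#' Generates `n_reps` samples for every combination of purity and noise
#' level, each from its own sub-seed derived from `seed`, so the whole
#' collection and every individual sample are exactly reproducible.
#'
#' @inheritParams simulate_cn_profile
#' @param purities vector of tumor fractions.
#' @param noise_levels vector of noise-level multipliers.
#' @param n_reps replicates per condition.
#' @param seed master integer seed.
#' @return A list of `"cn_sim"` objects; each carries `purity`,
#'   `noise_level`, `replicate` and `seed` fields.
#' @examples
#' ds <- simulate_cn_dataset(purities = 0.3, noise_levels = 1, n_reps = 2,
#'                           n_bins = 100, seed = 1)
#' length(ds)
#' @export
simulate_cn_dataset <- function(purities = seq(0.05, 0.5, by = 0.05),
                                noise_levels = c(0.5, 1, 2, 4),
                                n_reps = 50, n_bins = 1000,
                                base_noise_sd = 0.05, seed = 1, ...) {
  grid <- expand.grid(replicate = seq_len(n_reps), purity = purities,
                      noise_level = noise_levels)
  set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  out <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    s <- simulate_cn_profile(n_bins = n_bins, purity = grid$purity[k],
                             noise_level = grid$noise_level[k],
                             base_noise_sd = base_noise_sd,
                             seed = subseeds[k], ...)
    s$replicate <- grid$replicate[k]
    out[[k]] <- s
  }
  out
}

#' Write a simulated sample as a binned-profile TSV plus ground truth
#'
#' The observed values go to a four-column tab-separated table
#' (`chromosome`, `start`, `end`, `value`; 0-based half-open coordinates,
#' the dialect [read_bins()] reads), and the ground truth to a sidecar TSV
#' with columns `bin` (1-based) and `cn_state`.
#'
#' @param sim a `"cn_sim"` object.
#' @param path output path for the values table.
#' @param truth_path output path for the ground-truth table (default:
#'   `path` with a `.truth.tsv` suffix).
#' @param chrom chromosome name to use.
#' @param bin_size bin width in bp.
#' @return Invisibly, the two paths.
#' @export
write_simulated_sample <- function(sim, path,
                                   truth_path = paste0(path, ".truth.tsv"),
                                   chrom = "chr1", bin_size = 500000) {
  n <- length(sim$observed)
  vals <- data.frame(chromosome = chrom,
                     start = (seq_len(n) - 1L) * bin_size,
                     end = seq_len(n) * bin_size,
                     value = sim$observed)
  write.table(vals, path, sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- data.frame(bin = seq_len(n), cn_state = sim$cn_state)
  write.table(truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(path, truth_path))
}
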