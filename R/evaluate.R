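# Changepoint-detection metrics: tolerance-window precision/recall/F1 and
# normalized mutual information between segmentations.

#' Match predicted to true changepoints within a tolerance window
#'
#' Finds a one-to-one assignment between true and predicted changepoints in
#' which a pair may only be matched when the positions differ by at most
#' `tolerance` bins. Among all assignments the number of matched pairs is
#' maximized first (a greedy nearest-first rule can under-count true
#' positives), and among maximum-cardinality assignments the total distance
#' is minimized, preferring earlier pairs on ties. Each changepoint on
#' either side appears in at most one pair, so a single true changepoint
#' can never absorb several predictions.
#'
#' @param true_cps,predicted_cps sorted, duplicate-free integer positions.
#' @param tolerance maximal absolute distance, in bins, for a pair to count
#'   as a true positive.
#' @return A list with counts `tp`, `fp`, `fn` and `matched_pairs`, a
#'   two-column matrix of (true, predicted) positions.
#' @examples
#' match_changepoints(c(100, 200), c(101, 199, 300))
#' match_changepoints(c(10, 13), c(11, 12))  # both matched
#' @export
match_changepoints <- function(true_cps, predicted_cps, tolerance = 2) {
  t <- as.numeric(true_cps)
  p <- as.numeric(predicted_cps)
  for (v in list(t, p)) {
    if (anyDuplicated(v)) stop("changepoint lists must be duplicate-free",
                               call. = FALSE)
    if (is.unsorted(v)) stop("changepoint lists must be sorted",
                             call. = FALSE)
  }
  nt <- length(t)
  np <- length(p)
  # Eligible pairs form an interval bipartite graph, so a maximum matching
  # exists among non-crossing assignments; dynamic programming over the two
  # sorted lists maximizes matches and, within that, minimizes distance.
  count <- matrix(0L, nt + 1L, np + 1L)
  dist <- matrix(0, nt + 1L, np + 1L)
  move <- matrix(0L, nt + 1L, np + 1L)  # 1 skip true, 2 skip pred, 3 match
  for (i in seq_len(nt)) {
    for (j in seq_len(np)) {
      # skip true i
      bc <- count[i, j + 1L]; bd <- dist[i, j + 1L]; bm <- 1L
      # skip predicted j
      if (count[i + 1L, j] > bc ||
          (count[i + 1L, j] == bc && dist[i + 1L, j] < bd)) {
        bc <- count[i + 1L, j]; bd <- dist[i + 1L, j]; bm <- 2L
      }
      d <- abs(t[i] - p[j])
      if (d <= tolerance) {
        mc <- count[i, j] + 1L
        md <- dist[i, j] + d
        if (mc > bc || (mc == bc && md < bd)) {
          bc <- mc; bd <- md; bm <- 3L
        }
      }
      count[i + 1L, j + 1L] <- bc
      dist[i + 1L, j + 1L] <- bd
      move[i + 1L, j + 1L] <- bm
    }
  }
  pairs <- matrix(numeric(0), 0, 2,
                  dimnames = list(NULL, c("true", "predicted")))
  i <- nt; j <- np
  while (i > 0L && j > 0L) {
    m <- move[i + 1L, j + 1L]
    if (m == 3L) {
      pairs <- rbind(c(t[i], p[j]), pairs)
      i <- i - 1L; j <- j - 1L
    } else if (m == 1L) i <- i - 1L else j <- j - 1L
  }
  colnames(pairs) <- c("true", "predicted")
  tp <- count[nt + 1L, np + 1L]
  list(tp = as.integer(tp), fp = as.integer(np - tp),
       fn = as.integer(nt - tp), matched_pairs = pairs)
}

#' Precision, recall and F1 from a match result
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)` and
#' `F1 = 2 * precision * recall / (precision + recall)`. When no
#' changepoints were predicted (`TP + FP == 0`) the precision and F1 are
#' set to zero, reflecting the method's failure to detect anything rather
#' than leaving them undefined. Recall is `NA` when there are no true
#' changepoints (the simulations always contain at least one).
#'
#' @param match a match result from [match_changepoints()], or a list with
#'   `tp`, `fp`, `fn` counts.
#' @return A list with `precision`, `recall` and `f1`.
#' @examples
#' changepoint_metrics(list(tp = 1, fp = 1, fn = 1))
#' @export
changepoint_metrics <- function(match) {
  tp <- match$tp; fp <- match$fp; fn <- match$fn
  if (any(c(tp, fp, fn) < 0)) stop("counts must be non-negative",
                                   call. = FALSE)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  if (tp + fp == 0) {
    precision <- 0
    f1 <- 0
  } else {
    precision <- tp / (tp + fp)
    f1 <- if (!is.na(recall) && precision + recall > 0)
      2 * precision * recall / (precision + recall) else 0
  }
  list(precision = precision, recall = recall, f1 = f1)
}

#' Bin labels induced by a segmentation
#'
#' Bins between consecutive changepoints share a label; labels increase
#' from 0 left to right, giving `length(changepoints) + 1` distinct labels.
#'
#' @param changepoints sorted 1-based first-bin indices of segments after
#'   the first.
#' @param n_bins total number of bins.
#' @return Integer label per bin.
#' @examples
#' segmentation_labels(3, 4)
#' @export
segmentation_labels <- function(changepoints, n_bins) {
  cps <- as.integer(changepoints)
  if (length(cps) && (min(cps) < 2L || max(cps) > n_bins))
    stop("changepoints must lie in 2..n_bins", call. = FALSE)
  labels <- integer(n_bins)
  for (cp in cps) labels[cp:n_bins] <- labels[cp:n_bins] + 1L
  labels
}

#' Normalized mutual information between two segmentations
#'
#' `NMI(X, Y) = I(X, Y) / sqrt(H(X) * H(Y))` with plug-in (empirical)
#' entropies over the joint label distribution; the normalization base
#' cancels, natural logarithms are used. NMI is 1 for identical
#' partitions and 0 for independent ones. When either labeling has a
#' single segment its entropy is zero: the value is 1 if both labelings
#' are the single identical segment and `NA` (undefined) otherwise.
#'
#' @param labels_x,labels_y equal-length per-bin label vectors, e.g. from
#'   [segmentation_labels()].
#' @return NMI in \[0, 1\], or `NA` when undefined.
#' @examples
#' nmi(c(0, 0, 1, 1), c(0, 1, 1, 1))
#' @export
nmi <- function(labels_x, labels_y) {
  if (length(labels_x) != length(labels_y))
    stop("label vectors must have equal length", call. = FALSE)
  n <- length(labels_x)
  joint <- table(labels_x, labels_y) / n
  px <- rowSums(joint)
  py <- colSums(joint)
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  if (hx == 0 || hy == 0) {
    if (hx == 0 && hy == 0) return(1)  # both single-segment, identical
    return(NA_real_)
  }
  mi <- 0
  for (i in seq_along(px)) {
    for (j in seq_along(py)) {
      pij <- joint[i, j]
      if (pij > 0) mi <- mi + pij * log(pij / (px[i] * py[j]))
    }
  }
  max(min(mi / sqrt(hx * hy), 1), 0)
}

#' Benchmark segmentation accuracy on simulated profiles
#'
#' For every combination of noise level and purity, simulates `n_reps`
#' profiles, segments each with [bcpseg()], and scores the called against
#' the true changepoints with the tolerance-window matching rule. The whole
#' run is reproducible from the master seed.
#'
#' @inheritParams simulate_cn_dataset
#' @param n_reps replicates per condition.
#' @param tolerance matching window in bins (see [match_changepoints()]).
#' @param p0,w0,burnin,mcmc,epsilon,relative_epsilon,eta segmentation
#'   parameters passed to [bcpseg()].
#' @param verbose print one progress line per condition?
#' @return An object of class `"bcp_benchmark"`: a list with `results`
#'   (one row per sample: condition, replicate, seed, counts and metrics)
#'   and `summary` (per-condition means and SDs).
#' @examples
#' \donttest{
#' bm <- run_benchmark(purities = 0.3, noise_levels = 1, n_reps = 2,
#'                     n_bins = 300, burnin = 100, mcmc = 400, seed = 1)
#' bm$summary
#' }
#' @export
run_benchmark <- function(purities = seq(0.05, 0.5, by = 0.05),
                          noise_levels = c(0.5, 1, 2, 4), n_reps = 50,
                          n_bins = 1000, base_noise_sd = 0.05,
                          tolerance = 2, p0 = 0.01, w0 = 0.2,
                          burnin = 500, mcmc = 2000, epsilon = 0.05,
                          relative_epsilon = FALSE, eta = 0.5, seed = 1,
                          verbose = FALSE) {
  grid <- expand.grid(replicate = seq_len(n_reps), purity = purities,
                      noise_level = noise_levels)
  set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  rows <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    sim <- simulate_cn_profile(n_bins = n_bins, purity = grid$purity[k],
                               noise_level = grid$noise_level[k],
                               base_noise_sd = base_noise_sd,
                               seed = subseeds[k])
    fit <- bcpseg(sim$observed, p0 = p0, w0 = w0, burnin = burnin,
                  mcmc = mcmc, epsilon = epsilon,
                  relative_epsilon = relative_epsilon, eta = eta,
                  keep_draws = FALSE)
    m <- match_changepoints(sim$changepoints, fit$changepoints, tolerance)
    met <- changepoint_metrics(m)
    rows[[k]] <- data.frame(noise_level = grid$noise_level[k],
                            purity = grid$purity[k],
                            replicate = grid$replicate[k],
                            seed = subseeds[k],
                            n_true = length(sim$changepoints),
                            n_predicted = length(fit$changepoints),
                            tp = m$tp, fp = m$fp, fn = m$fn,
                            precision = met$precision,
                            recall = met$recall, f1 = met$f1)
    if (verbose && grid$replicate[k] == n_reps)
      message(sprintf("noise %g, purity %.2f: mean F1 so far computed",
                      grid$noise_level[k], grid$purity[k]))
  }
  results <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(
    split(results, list(results$noise_level, results$purity), drop = TRUE),
    function(d) data.frame(noise_level = d$noise_level[1],
                           purity = d$purity[1], n = nrow(d),
                           mean_f1 = mean(d$f1), sd_f1 = sd(d$f1),
                           mean_precision = mean(d$precision),
                           mean_recall = mean(d$recall))))
  agg <- agg[order(agg$noise_level, agg$purity), ]
  rownames(agg) <- NULL
  out <- list(results = results, summary = agg,
              params = list(tolerance = tolerance, p0 = p0, w0 = w0,
                            burnin = burnin, mcmc = mcmc, epsilon = epsilon,
                            eta = eta, base_noise_sd = base_noise_sd,
                            n_bins = n_bins, seed = seed))
  class(out) <- "bcp_benchmark"
  out
}

#' @export
print.bcp_benchmark <- function(x, ...) {
  cat("Segmentation benchmark on simulated profiles\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write benchmark results to disk
#'
#' The per-sample table goes to a tidy TSV (one row per sample) and the
#' per-condition means to a JSON summary.
#'
#' @param benchmark a `"bcp_benchmark"` object.
#' @param tsv_path,json_path output paths; either may be `NULL` to skip.
#' @return Invisibly, the written paths.
#' @export
write_benchmark <- function(benchmark, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path))
    write.table(benchmark$results, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(benchmark$summary, json_path, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  invisible(c(tsv_path, json_path))
}

#' @importFrom stats sd
NULL
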