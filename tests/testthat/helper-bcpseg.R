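# Shared test fixtures and independent oracles. Everything here is a
# deliberately naive reference implementation, kept separate from the
# package's own code paths.

# exhaustive one-to-one matching: maximize matched pairs, then minimize
# total distance (reference for match_changepoints)
brute_force_match <- function(true_cps, pred_cps, tolerance) {
  best <- c(0, Inf)
  np <- length(pred_cps)
  recurse <- function(i, used, matches, dist) {
    if (i > length(true_cps)) {
      if (matches > best[1] || (matches == best[1] && dist < best[2]))
        best <<- c(matches, dist)
      return(invisible(NULL))
    }
    recurse(i + 1L, used, matches, dist)  # leave true i unmatched
    for (j in seq_len(np)) {
      d <- abs(true_cps[i] - pred_cps[j])
      if (!used[j] && d <= tolerance) {
        used[j] <- TRUE
        recurse(i + 1L, used, matches + 1L, dist + d)
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(np), 0L, 0)
  list(tp = as.integer(best[1]), dist = best[2])
}

# NMI through the entropy identity I(X,Y) = H(X) + H(Y) - H(X,Y)
nmi_independent <- function(a, b) {
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  n <- length(a)
  hx <- ent(table(a) / n)
  hy <- ent(table(b) / n)
  hxy <- ent(table(paste(a, b)) / n)
  (hx + hy - hxy) / sqrt(hx * hy)
}

# two-level step profile with Gaussian noise
step_profile <- function(n, boundary, delta, sd) {
  c(rnorm(boundary, 0, sd), rnorm(n - boundary, delta, sd))
}

# small binned profile on two chromosomes for IO tests
toy_bins <- function(values1, values2, bin_size = 1000L) {
  n1 <- length(values1)
  n2 <- length(values2)
  binned_profile(
    chrom = c(rep("chr1", n1), rep("chr2", n2)),
    start = c(seq_len(n1) - 1L, seq_len(n2) - 1L) * bin_size,
    end = c(seq_len(n1), seq_len(n2)) * bin_size,
    value = c(values1, values2))
}
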