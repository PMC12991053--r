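# S3 methods for the fitted "bcpseg" object.

#' @export
print.bcpseg <- function(x, ...) {
  cat("Bayesian changepoint segmentation\n")
  nseg <- nrow(x$segments)
  ncp <- length(x$changepoints)
  nbin <- if (!is.null(x$bins)) nrow(x$bins) else length(x$data)
  cat(sprintf("  %d bins, %d segments (%d changepoints)\n", nbin, nseg, ncp))
  cat(sprintf("  noise scale (MAD): %s\n",
              paste(signif(x$sigma, 4), collapse = ", ")))
  p <- x$params
  cat(sprintf("  p0 = %g, w0 = %g, sweeps = %d + %d, epsilon = %g%s, eta = %g\n",
              p$p0, p$w0, p$burnin, p$mcmc, p$epsilon,
              if (p$relative_epsilon) " (relative)" else "", p$eta))
  invisible(x)
}

#' @export
summary.bcpseg <- function(object, ...) {
  cat("Segments:\n")
  print(object$segments, row.names = FALSE)
  cat("\nChangepoints (first bin of each new segment):",
      if (length(object$changepoints)) paste(object$changepoints,
                                             collapse = ", ") else "none",
      "\n")
  invisible(object)
}

#' Per-bin fitted values of a segmented profile
#'
#' Each bin receives the median of its segment; masked bins of a genomic
#' input are `NA`.
#' @param object a fitted `"bcpseg"` object.
#' @param ... unused.
#' @export
fitted.bcpseg <- function(object, ...) {
  if (!is.null(object$bins)) {
    out <- rep(NA_real_, nrow(object$bins))
    for (ch in unique(object$segments$chrom)) {
      segs <- object$segments[object$segments$chrom == ch, ]
      sel <- which(object$bins$chrom == ch & !is.na(object$bins$value))
      out[sel] <- rep(segs$value, segs$n_bins)
    }
    out
  } else {
    segs <- object$segments
    rep(segs$value, segs$n_bins)
  }
}

#' @export
residuals.bcpseg <- function(object, ...) {
  obs <- if (!is.null(object$bins)) object$bins$value else object$data
  obs - fitted(object)
}

#' @export
coef.bcpseg <- function(object, ...) {
  object$segments$value
}

#' Diagnostic plot of a segmented profile
#'
#' Three stacked panels: the observations with the posterior mean and 95%
#' credible band; the posterior changepoint probabilities with the filter
#' threshold and the called changepoints; and the reconstructed segmented
#' profile. This is the plot to inspect when choosing `epsilon`: a
#' threshold cutting through the noise floor of the probability track is
#' low enough, one clipping genuine peaks is too high.
#'
#' @param x a fitted `"bcpseg"` object.
#' @param ... passed to the top panel's `plot`.
#' @export
plot.bcpseg <- function(x, ...) {
  obs <- if (!is.null(x$bins)) x$bins$value else x$data
  n <- length(obs)
  fit <- fitted(x)
  op <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  plot(obs, pch = 16, cex = 0.4, col = "grey40", xlab = "",
       ylab = "value", main = "observations and posterior mean", ...)
  if (!all(is.na(x$ci_lower))) {
    ok <- !is.na(x$ci_lower)
    graphics::polygon(c(which(ok), rev(which(ok))),
                      c(x$ci_lower[ok], rev(x$ci_upper[ok])),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
  }
  graphics::lines(x$posterior_mean, col = "steelblue", lwd = 1.5)
  eps <- x$params$epsilon
  if (x$params$relative_epsilon)
    eps <- eps * max(x$posterior_prob[-n], 0, na.rm = TRUE)
  plot(x$posterior_prob, type = "h", col = "grey40", ylim = c(0, 1),
       xlab = "", ylab = "P(changepoint)",
       main = "posterior changepoint probabilities")
  graphics::abline(h = eps, lty = 2, col = "firebrick")
  graphics::abline(v = x$changepoints - 0.5, col = "firebrick", lwd = 0.5)
  plot(obs, pch = 16, cex = 0.4, col = "grey70", xlab = "bin",
       ylab = "value", main = "reconstructed profile")
  graphics::lines(fit, col = "firebrick", lwd = 2)
  invisible(x)
}
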