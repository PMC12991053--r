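# Reading binned genomic profiles and writing segment calls.
#
# Internal coordinates are 0-based half-open (the bedGraph convention);
# the SEG output follows the common 1-based inclusive dialect.

#' Read a binned genomic profile
#'
#' Reads either a four-column bedGraph track (`chrom start end value`,
#' 0-based half-open, no header; `track`/`#` lines ignored) or a headered
#' tab-separated table with chromosome/start/end columns and one value
#' column — the dialect exported by standard low-pass WGS preprocessors.
#' For headered tables the coordinate dialect is auto-detected: when
#' consecutive bins satisfy `start[k+1] == end[k] + 1` the coordinates are
#' taken as 1-based inclusive and converted. Non-numeric or NA value
#' tokens become missing values, which are tracked and excluded from
#' sampling, never imputed.
#'
#' @param path input file.
#' @param format `"auto"` (by content), `"tsv"` or `"bedgraph"`.
#' @return A data frame of class `"binned_profile"` with columns `chrom`,
#'   `start` (0-based), `end` (exclusive) and `value`, plus attributes
#'   `bin_size` and `source`.
#' @export
read_bins <- function(path, format = c("auto", "tsv", "bedgraph")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 50L, warn = FALSE)
  first <- first[!grepl("^(track|browser|#)", first) & nzchar(first)]
  if (!length(first)) stop("no data lines in ", path, call. = FALSE)
  fields <- strsplit(first[1], "\t", fixed = TRUE)[[1]]
  looks_headered <- suppressWarnings(is.na(as.numeric(fields[2])))
  if (format == "auto")
    format <- if (looks_headered) "tsv" else "bedgraph"

  if (format == "bedgraph") {
    if (requireNamespace("rtracklayer", quietly = TRUE)) {
      gr <- as.data.frame(rtracklayer::import(path, format = "bedGraph"))
      df <- data.frame(chrom = as.character(gr$seqnames),
                       start = gr$start - 1L,
                       end = gr$end,
                       value = gr$score)
    } else {
      raw <- read.delim(path, header = FALSE, comment.char = "#",
                        stringsAsFactors = FALSE)
      raw <- raw[!grepl("^(track|browser)", raw[[1]]), , drop = FALSE]
      if (ncol(raw) < 4L)
        stop("bedGraph needs four columns", call. = FALSE)
      df <- data.frame(chrom = as.character(raw[[1]]),
                       start = as.integer(raw[[2]]),
                       end = as.integer(raw[[3]]),
                       value = suppressWarnings(as.numeric(raw[[4]])))
    }
  } else {
    raw <- read.delim(path, stringsAsFactors = FALSE)
    nm <- tolower(names(raw))
    ci <- which(nm %in% c("chromosome", "chrom", "chr", "seqnames"))[1]
    si <- which(nm %in% c("start", "pos", "bin_start"))[1]
    ei <- which(nm %in% c("end", "stop", "bin_end"))[1]
    if (any(is.na(c(ci, si, ei))))
      stop("could not identify chromosome/start/end columns in ", path,
           call. = FALSE)
    vi <- setdiff(seq_along(raw), c(ci, si, ei))
    vi <- vi[vapply(raw[vi], function(col)
      is.numeric(col) || all(is.na(suppressWarnings(as.numeric(col))) ==
                               is.na(col) | col %in% c("NA", "")),
      logical(1))][1]
    if (is.na(vi))
      stop("could not identify a numeric value column in ", path,
           call. = FALSE)
    df <- data.frame(chrom = as.character(raw[[ci]]),
                     start = as.integer(raw[[si]]),
                     end = as.integer(raw[[ei]]),
                     value = suppressWarnings(as.numeric(raw[[vi]])))
    # 1-based inclusive dialect: next start = previous end + 1
    same <- df$chrom[-1] == df$chrom[-nrow(df)]
    if (nrow(df) > 1 && any(same) &&
        all((df$start[-1] == df$end[-nrow(df)] + 1L)[same]))
      df$start <- df$start - 1L
  }
  .validate_bins(df, path)
}

.validate_bins <- function(df, source = "input") {
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, ]
    if (is.unsorted(d$start))
      stop("bins on ", ch, " are not sorted", call. = FALSE)
    if (any(d$start[-1] < d$end[-nrow(d)]))
      stop("bins on ", ch, " overlap", call. = FALSE)
    widths <- d$end - d$start
    if (any(widths <= 0))
      stop("non-positive bin width on ", ch, call. = FALSE)
    if (nrow(d) > 2 && length(unique(widths[-nrow(d)])) > 1)
      stop("inconsistent bin widths on ", ch,
           " (only the last bin may be short)", call. = FALSE)
  }
  attr(df, "bin_size") <- max(df$end - df$start)
  attr(df, "source") <- source
  class(df) <- c("binned_profile", "data.frame")
  df
}

#' Construct a binned profile from vectors
#'
#' Convenience constructor for in-memory data; applies the same validation
#' as [read_bins()].
#'
#' @param chrom chromosome per bin.
#' @param start,end 0-based half-open coordinates per bin.
#' @param value per-bin value (`NA` for masked bins).
#' @return A `"binned_profile"` data frame.
#' @export
binned_profile <- function(chrom, start, end, value) {
  .validate_bins(data.frame(chrom = as.character(chrom),
                            start = as.integer(start),
                            end = as.integer(end),
                            value = as.numeric(value)),
                 source = "constructed")
}

#' Write segment calls and the probability track
#'
#' Writes the segments of a fitted genomic profile as a SEG-style
#' tab-separated table (`sample`, `chromosome`, `start`, `end`,
#' `num_bins`, `seg_value`; 1-based inclusive coordinates, noted in a
#' header comment) and, optionally, the per-bin posterior changepoint
#' probabilities as a bedGraph track (0-based half-open).
#'
#' @param fit a `"bcpseg"` object fitted to a `"binned_profile"`.
#' @param seg_path output path of the SEG table.
#' @param prob_path optional output path of the probability bedGraph.
#' @param sample sample name for the first SEG column.
#' @return Invisibly, the written paths.
#' @export
write_segments <- function(fit, seg_path, prob_path = NULL,
                           sample = "sample") {
  if (!inherits(fit, "bcpseg") || is.null(fit$bins))
    stop("'fit' must be a bcpseg fit of a binned genomic profile",
         call. = FALSE)
  segs <- fit$segments
  seg_out <- data.frame(sample = sample,
                        chromosome = segs$chrom,
                        start = segs$genomic_start + 1L,
                        end = segs$genomic_end,
                        num_bins = segs$n_bins,
                        seg_value = segs$value)
  con <- file(seg_path, "w")
  writeLines("# coordinates: 1-based inclusive", con)
  write.table(seg_out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  if (!is.null(prob_path)) {
    ok <- !is.na(fit$posterior_prob)
    prob_out <- data.frame(chrom = fit$bins$chrom[ok],
                           start = fit$bins$start[ok],
                           end = fit$bins$end[ok],
                           value = fit$posterior_prob[ok])
    con <- file(prob_path, "w")
    writeLines("track type=bedGraph name=posterior_changepoint_probability",
               con)
    write.table(prob_out, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    close(con)
  }
  invisible(c(seg_path, prob_path))
}
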