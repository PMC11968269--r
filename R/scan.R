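#' Partition a genome into fixed-width bins
#'
#' Tiles each chromosome with half-open bins of width `width`. In the
#' default non-overlapping mode (`step == width`) the last bin per
#' chromosome may be short; with `step < width` a sliding-window mode is
#' produced (windows start every `step` bp and overlap).
#'
#' @param genome data.frame with columns `chrom` and `length` (bp), or a
#'   named numeric vector of chromosome lengths.
#' @param width Bin width in bp (default 1 Mb).
#' @param step Start-to-start distance between bins; defaults to `width`
#'   (non-overlapping).
#' @return data.frame of class `bin_table` with columns `chrom`, `start`,
#'   `end`; the genome, width and step are kept as attributes.
#' @export
bin_genome <- function(genome, width = 1e6, step = width) {
  if (width <= 0 || step <= 0) stop("width and step must be positive")
  if (!is.data.frame(genome))
    genome <- data.frame(chrom = names(genome), length = as.numeric(genome),
                         stringsAsFactors = FALSE)
  if (anyDuplicated(genome$chrom)) stop("duplicate chromosome names")
  if (any(genome$length <= 0)) stop("chromosome lengths must be positive")
  out <- do.call(rbind, lapply(seq_len(nrow(genome)), function(i) {
    len <- genome$length[i]
    starts <- seq(0, len - 1, by = step)
    data.frame(chrom = genome$chrom[i], start = starts,
               end = pmin(starts + width, len), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "genome") <- genome
  attr(out, "width") <- width
  attr(out, "step") <- step
  class(out) <- c("bin_table", "data.frame")
  out
}

#' Count hit anchors per bin
#'
#' Assigns each hit (a single anchor position, e.g. a downregulated gene's
#' 5'-UTR coordinate) to the bins containing it: exactly one bin in
#' non-overlapping mode, possibly several in sliding mode. Bin intervals
#' are half-open, so an anchor exactly at a bin boundary belongs to the bin
#' starting there.
#'
#' @param bins A `bin_table` from [bin_genome()].
#' @param hits data.frame with columns `chrom` and `pos` (0-based bp), or a
#'   numeric vector of positions on a single-chromosome genome.
#' @return The `bin_table` with a hit-count column `k` added.
#' @export
count_hits <- function(bins, hits) {
  genome <- attr(bins, "genome")
  if (!is.data.frame(hits)) {
    if (nrow(genome) != 1)
      stop("bare positions need a single-chromosome genome")
    hits <- data.frame(chrom = rep(genome$chrom[1], length(hits)),
                       pos = as.numeric(hits), stringsAsFactors = FALSE)
  }
  bad_chr <- setdiff(unique(hits$chrom), genome$chrom)
  if (length(bad_chr)) stop("hits on unknown chromosome(s): ",
                            paste(bad_chr, collapse = ", "))
  len <- genome$length[match(hits$chrom, genome$chrom)]
  if (any(hits$pos < 0 | hits$pos >= len))
    stop("hit anchor outside the genome")
  k <- integer(nrow(bins))
  for (chr in unique(hits$chrom)) {
    bi <- which(bins$chrom == chr)
    p <- hits$pos[hits$chrom == chr]
    pt <- IRanges::IRanges(start = as.integer(p) + 1L, width = 1L)
    br <- IRanges::IRanges(start = as.integer(bins$start[bi]) + 1L,
                           end = as.integer(bins$end[bi]))
    k[bi] <- IRanges::countOverlaps(br, pt)
  }
  bins$k <- k
  bins
}

#' Poisson enrichment scan over genome bins
#'
#' Fits a single genome-wide Poisson rate by maximum likelihood
#' (`lambda = total hits / number of bins`, the mean occurrence count) and
#' computes, for every bin, the upper-tail probability `P(X >= k)` in log
#' space (numerically stable far below 1e-300), the fold enrichment
#' `k / lambda`, and a convenience BH-adjusted column (the ranking uses the
#' raw Poisson p).
#'
#' @param bins A `bin_table` with counts, from [count_hits()].
#' @param denominator_bins Optional logical vector: which bins enter the
#'   rate denominator (e.g. only gene-bearing bins); hits falling in
#'   excluded bins are also excluded from the numerator. Default: all bins.
#' @return data.frame of class `bin_enrichment`: `chrom`, `start`, `end`,
#'   `k`, `lambda`, `fold`, `p`, `log10p` (= -log10 p, finite even when
#'   `p` underflows), `padj`.
#' @export
poisson_scan <- function(bins, denominator_bins = NULL) {
  if (nrow(bins) == 0) stop("no bins to scan")
  if (!"k" %in% names(bins)) stop("bins carry no hit counts; run count_hits()")
  use <- if (is.null(denominator_bins)) rep(TRUE, nrow(bins))
         else denominator_bins
  stopifnot(length(use) == nrow(bins))
  lambda <- sum(bins$k[use]) / sum(use)
  logp <- stats::ppois(bins$k - 1, lambda, lower.tail = FALSE, log.p = TRUE)
  out <- data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                    k = bins$k, lambda = lambda,
                    fold = if (lambda > 0) bins$k / lambda else NA_real_,
                    p = exp(logp), log10p = -logp / log(10),
                    stringsAsFactors = FALSE)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  class(out) <- c("bin_enrichment", "data.frame")
  out
}

#' Ranked Manhattan table
#'
#' Orders scan results in genomic plotting order (chromosome, then start),
#' adds a cumulative plotting coordinate and a significance rank
#' (increasing p; ties broken by genomic position).
#'
#' @param scan A `bin_enrichment` from [poisson_scan()].
#' @return data.frame in plotting order with added columns `pos_cum` and
#'   `rank`; the top bin (rank 1) is attached as attribute `top_bin`.
#' @export
manhattan_table <- function(scan) {
  if (nrow(scan) == 0) {
    out <- cbind(scan, pos_cum = numeric(0), rank = integer(0))
    attr(out, "top_bin") <- NULL
    return(out)
  }
  ord <- order(scan$chrom, scan$start)
  out <- scan[ord, , drop = FALSE]
  offsets <- c(0, cumsum(tapply(out$end, out$chrom, max)))
  out$pos_cum <- out$start + offsets[match(out$chrom,
                                           unique(out$chrom))]
  # rank by decreasing significance; ties resolved by plotting order
  out$rank <- order(order(-out$log10p, seq_len(nrow(out))))
  rownames(out) <- NULL
  attr(out, "top_bin") <- out[out$rank == 1, , drop = FALSE]
  out
}

#' Manhattan plot of a Poisson scan
#'
#' Base-graphics Manhattan plot of per-bin `-log10 p` against cumulative
#' genomic position, alternating color by chromosome.
#'
#' @param scan A `bin_enrichment`.
#' @param ... Passed to [plot()].
#' @return Invisibly, the ranked table.
#' @export
plot_manhattan <- function(scan, ...) {
  tab <- manhattan_table(scan)
  chr_i <- match(tab$chrom, unique(tab$chrom))
  plot(tab$pos_cum, tab$log10p, pch = 16, cex = 0.6,
       col = c("grey30", "steelblue")[1 + chr_i %% 2],
       xlab = "genomic position", ylab = expression(-log[10] * " p"), ...)
  invisible(tab)
}
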