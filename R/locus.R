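#' Configuration for the synthetic clustered locus
#'
#' Builds the settings list consumed by [build_locus_annotation()]. The
#' defaults emulate a clustered-protocadherin-like locus: three tandem gene
#' clusters (14 alpha + 22 beta + 22 gamma = 58 genes) spanning roughly one
#' megabase, followed downstream by a block of named enhancer elements
#' (HS7, HS5-1, HS7L, HS5-1bL, HS18-20, HS21, HS22), embedded in a single
#' synthetic chromosome with evenly spaced background genes for the
#' genome-wide enrichment-scan null.
#'
#' All coordinates are 0-based, half-open (BED convention).
#'
#' @param chrom Chromosome name.
#' @param chrom_length Chromosome length in bp.
#' @param locus_start Start of the locus (bp; position of the first gene
#'   anchor).
#' @param cluster_sizes Named integer vector of gene counts for the alpha,
#'   beta and gamma clusters.
#' @param gene_spacing Distance between consecutive gene anchors within a
#'   cluster (bp).
#' @param intercluster_gap Extra gap inserted between clusters (bp).
#' @param exon_length Length of each gene's variable-exon interval (bp).
#' @param enhancer_gap Gap between the last gene anchor and the first
#'   enhancer element (bp).
#' @param enhancer_offsets Named numeric vector of enhancer start offsets
#'   (bp) relative to the last gene anchor + `enhancer_gap`.
#' @param enhancer_widths Named numeric vector of enhancer widths (bp).
#' @param n_background Number of background genes spread over the rest of
#'   the chromosome (may be 0).
#' @param background_gene_length Length of background gene intervals (bp).
#' @return A list of class `locus_config`.
#' @export
locus_config <- function(chrom = "chrS",
                         chrom_length = 1e8,
                         locus_start = 6e7,
                         cluster_sizes = c(alpha = 14L, beta = 22L, gamma = 22L),
                         gene_spacing = 15000,
                         intercluster_gap = 40000,
                         exon_length = 2400,
                         enhancer_gap = 25000,
                         enhancer_offsets = c("HS7" = 0, "HS5-1" = 20000,
                                              "HS7L" = 45000, "HS5-1bL" = 60000,
                                              "HS18-20" = 75000, "HS21" = 90000,
                                              "HS22" = 100000),
                         enhancer_widths = c("HS7" = 2000, "HS5-1" = 2000,
                                             "HS7L" = 2000, "HS5-1bL" = 2000,
                                             "HS18-20" = 6000, "HS21" = 2000,
                                             "HS22" = 2000),
                         n_background = 2000L,
                         background_gene_length = 2000) {
  stopifnot(chrom_length > 0, locus_start >= 0, gene_spacing > 0,
            exon_length > 0, n_background >= 0)
  if (!identical(names(cluster_sizes), c("alpha", "beta", "gamma")))
    stop("cluster_sizes must be named alpha, beta, gamma (in order)")
  if (!setequal(names(enhancer_offsets), names(enhancer_widths)))
    stop("enhancer_offsets and enhancer_widths must name the same elements")
  structure(list(chrom = chrom, chrom_length = chrom_length,
                 locus_start = locus_start, cluster_sizes = cluster_sizes,
                 gene_spacing = gene_spacing,
                 intercluster_gap = intercluster_gap,
                 exon_length = exon_length, enhancer_gap = enhancer_gap,
                 enhancer_offsets = enhancer_offsets,
                 enhancer_widths = enhancer_widths,
                 n_background = as.integer(n_background),
                 background_gene_length = background_gene_length),
            class = "locus_config")
}

#' Build the synthetic locus annotation
#'
#' Deterministically lays out the clustered genes, enhancer elements and
#' background genes described by a [locus_config()]. Gene anchors (the
#' 5'-UTR positions used for every distance computation) increase strictly
#' in the order alpha, beta, gamma, and all enhancer elements lie downstream
#' of every clustered gene, so the beta cluster is farther from its assigned
#' enhancer set (HS18-22) than the gamma cluster is from its set (HS5-1bL).
#' Background genes are evenly spaced over the chromosome outside the locus.
#'
#' @param config A [locus_config()].
#' @return A list of class `locus_annotation` with components
#'   `genes` (data.frame: id, cluster, chrom, strand, anchor, exon_start,
#'   exon_end, length), `enhancers` (data.frame: name, chrom, start, end),
#'   `genome` (data.frame: chrom, length) and `config`.
#' @export
build_locus_annotation <- function(config = locus_config()) {
  stopifnot(inherits(config, "locus_config"))
  cs <- config$cluster_sizes
  n_genes <- sum(cs)
  cluster <- rep(names(cs), times = cs)
  within_idx <- unlist(lapply(cs, seq_len), use.names = FALSE)
  # anchors: uniform spacing, extra gap between clusters
  gap_before <- c(0, config$intercluster_gap,
                  config$intercluster_gap)[match(cluster, names(cs))] *
    (within_idx == 1) * (cluster != "alpha")
  anchor <- config$locus_start +
    (seq_len(n_genes) - 1) * config$gene_spacing + cumsum(gap_before)
  id <- paste0("Pcdh", c(alpha = "a", beta = "b", gamma = "g")[cluster],
               within_idx)
  genes <- data.frame(id = id, cluster = cluster, chrom = config$chrom,
                      strand = "+", anchor = anchor,
                      exon_start = anchor,
                      exon_end = anchor + config$exon_length,
                      length = config$exon_length,
                      stringsAsFactors = FALSE)

  enh_base <- max(anchor) + config$enhancer_gap
  off <- config$enhancer_offsets
  wid <- config$enhancer_widths[names(off)]
  enhancers <- data.frame(name = names(off), chrom = config$chrom,
                          start = enh_base + unname(off),
                          end = enh_base + unname(off) + unname(wid),
                          stringsAsFactors = FALSE)
  enhancers <- enhancers[order(enhancers$start), , drop = FALSE]
  rownames(enhancers) <- NULL

  # reject configurations whose gene or enhancer intervals overlap
  iv <- rbind(cbind(genes$exon_start, genes$exon_end),
              cbind(enhancers$start, enhancers$end))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  if (any(iv[-1, 1] < iv[-nrow(iv), 2]))
    stop("config produces overlapping gene/enhancer intervals")
  if (max(iv[, 2]) > config$chrom_length)
    stop("locus extends beyond the chromosome")

  if (config$n_background > 0) {
    bg_anchor <- .background_positions(config$n_background,
                                       config$chrom_length,
                                       config$locus_start, max(iv[, 2]),
                                       config$background_gene_length)
    bg <- data.frame(id = sprintf("bg%04d", seq_along(bg_anchor)),
                     cluster = "background", chrom = config$chrom,
                     strand = "+", anchor = bg_anchor,
                     exon_start = bg_anchor,
                     exon_end = bg_anchor + config$background_gene_length,
                     length = config$background_gene_length,
                     stringsAsFactors = FALSE)
    genes <- rbind(genes, bg)
  }
  rownames(genes) <- NULL
  structure(list(genes = genes, enhancers = enhancers,
                 genome = data.frame(chrom = config$chrom,
                                     length = config$chrom_length,
                                     stringsAsFactors = FALSE),
                 config = config),
            class = "locus_annotation")
}

# Evenly spaced positions over [0, chrom_length) excluding the locus span,
# allocated to the two flanking segments proportionally to their lengths.
.background_positions <- function(n, chrom_length, locus_start, locus_end,
                                  gene_length) {
  pad <- 50000  # keep background genes clear of the locus
  seg <- rbind(c(0, max(0, locus_start - pad)),
               c(min(chrom_length, locus_end + pad), chrom_length))
  seg_len <- pmax(0, seg[, 2] - seg[, 1] - gene_length)
  n_seg <- round(n * seg_len / sum(seg_len))
  n_seg[1] <- n - n_seg[2]
  pos <- unlist(lapply(which(n_seg > 0), function(i) {
    k <- n_seg[i]
    seg[i, 1] + (seq_len(k) - 0.5) / k * seg_len[i]
  }), use.names = FALSE)
  floor(pos)
}

#' @export
print.locus_annotation <- function(x, ...) {
  cs <- table(factor(x$genes$cluster,
                     levels = c("alpha", "beta", "gamma", "background")))
  cat("Synthetic clustered locus on", x$genome$chrom,
      sprintf("(%.0f bp)\n", x$genome$length))
  cat("  genes:", paste(sprintf("%s=%d", names(cs), cs), collapse = ", "), "\n")
  cat("  enhancers:", paste(x$enhancers$name, collapse = ", "), "\n")
  loc <- x$genes[x$genes$cluster != "background", ]
  cat(sprintf("  locus span: %.0f-%.0f bp\n", min(loc$anchor),
              max(x$enhancers$end)))
  invisible(x)
}
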