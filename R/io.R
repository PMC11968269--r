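# Plain-text interchange. All package coordinates are natively 0-based
# half-open, i.e. already in BED convention; BED/bedGraph are therefore
# written/read without coordinate shifts. Contact matrices go out as
# Matrix Market triplets plus a bin BED.

#' Write annotation as BED plus TSV sidecar
#'
#' Genes go to `<prefix>_genes.bed` (chrom, start, end, name, score=0,
#' strand) with a sidecar `<prefix>_genes.tsv` (id, cluster, anchor,
#' length); enhancers to `<prefix>_enhancers.bed`.
#'
#' @param annotation A `locus_annotation`.
#' @param prefix Output path prefix.
#' @return Invisibly, the written file paths.
#' @export
write_annotation <- function(annotation, prefix) {
  g <- annotation$genes
  gene_bed <- data.frame(g$chrom, g$exon_start, g$exon_end, g$id, 0L,
                         g$strand)
  f1 <- paste0(prefix, "_genes.bed")
  utils::write.table(gene_bed, f1, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  f2 <- paste0(prefix, "_genes.tsv")
  utils::write.table(g[, c("id", "cluster", "anchor", "length")], f2,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  e <- annotation$enhancers
  f3 <- paste0(prefix, "_enhancers.bed")
  utils::write.table(data.frame(e$chrom, e$start, e$end, e$name), f3,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(c(f1, f2, f3))
}

#' Write a counts table as TSV (genes x samples)
#'
#' @param x A `count_matrix` or plain matrix.
#' @param path Output path.
#' @export
write_counts <- function(x, path) {
  m <- if (inherits(x, "count_matrix")) x$counts else x
  utils::write.table(data.frame(id = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a counts TSV written by [write_counts()]
#'
#' @param path Input path.
#' @return Integer matrix with gene ids as rownames.
#' @export
read_counts <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}

#' Write a contact matrix as Matrix Market triplets plus a bin BED
#'
#' The upper triangle (including the diagonal) of the symmetric matrix is
#' written as a sparse symmetric MatrixMarket file `<prefix>.mtx`; bin
#' coordinates go to `<prefix>_bins.bed`.
#'
#' @param mat A [contact_matrix()].
#' @param prefix Output path prefix.
#' @return Invisibly, the written paths.
#' @export
write_contact_matrix <- function(mat, prefix) {
  stopifnot(inherits(mat, "contact_matrix"))
  sp <- methods::as(methods::as(Matrix::Matrix(mat$counts), "symmetricMatrix"),
                    "TsparseMatrix")
  f1 <- paste0(prefix, ".mtx")
  Matrix::writeMM(sp, f1)
  n <- nrow(mat$counts)
  bins <- data.frame(mat$chrom,
                     mat$start + (seq_len(n) - 1) * mat$bin_size,
                     mat$start + seq_len(n) * mat$bin_size,
                     paste0("bin", seq_len(n)))
  f2 <- paste0(prefix, "_bins.bed")
  utils::write.table(bins, f2, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(f1, f2))
}

#' Read a contact matrix written by [write_contact_matrix()]
#'
#' @param prefix Path prefix used at write time.
#' @return A [contact_matrix()].
#' @export
read_contact_matrix <- function(prefix) {
  sp <- Matrix::readMM(paste0(prefix, ".mtx"))
  m <- as.matrix(sp)
  bins <- utils::read.table(paste0(prefix, "_bins.bed"), sep = "\t",
                            stringsAsFactors = FALSE)
  contact_matrix(m, bin_size = bins[1, 3] - bins[1, 2],
                 chrom = bins[1, 1], start = bins[1, 2])
}

#' Write a signal track as bedGraph
#'
#' @param track data.frame with columns `chrom` (optional), `start`, `end`,
#'   `value`.
#' @param path Output path.
#' @param chrom Chromosome name used if the track has no `chrom` column.
#' @export
write_bedgraph <- function(track, path, chrom = "chrS") {
  if (!"chrom" %in% names(track)) track$chrom <- chrom
  keep <- !is.na(track$value)
  utils::write.table(track[keep, c("chrom", "start", "end", "value")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph track
#'
#' @param path Input path.
#' @return data.frame with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  d <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(d) <- c("chrom", "start", "end", "value")
  d
}

#' Write TAD calls as BED
#'
#' @param tads A `tad_set` whose domains carry bp coordinates.
#' @param path Output path.
#' @param chrom Chromosome name.
#' @export
write_tads_bed <- function(tads, path, chrom = "chrS") {
  d <- tads$domains
  if (!all(c("start_bp", "end_bp") %in% names(d)))
    stop("call_tads() needs the di profile to attach bp coordinates")
  utils::write.table(
    data.frame(chrom, d$start_bp, d$end_bp,
               paste0("TAD", seq_len(nrow(d)))),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
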