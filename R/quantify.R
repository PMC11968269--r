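#' FPKM from a count matrix
#'
#' Fragments per kilobase per million mapped reads:
#' `FPKM = counts * 1e9 / (length_bp * mapped_total)`, computed per sample.
#' For a [simulate_expression()] result the recorded nominal library sizes
#' are used as the denominator; a plain matrix needs explicit `lengths`
#' and `totals`.
#'
#' @param x A `count_matrix` (from [simulate_expression()]) or a numeric
#'   matrix of counts (features x samples).
#' @param lengths Feature lengths in bp (recycled names must match rows).
#' @param totals Per-sample mapped totals (reads).
#' @return Numeric matrix of FPKM values, same dimnames as the counts.
#' @export
compute_fpkm <- function(x, lengths = NULL, totals = NULL) {
  if (inherits(x, "count_matrix")) {
    counts <- x$counts
    if (is.null(lengths)) lengths <- x$lengths
    if (is.null(totals)) totals <- x$library_sizes
  } else counts <- as.matrix(x)
  lengths <- rep_len(as.numeric(lengths), nrow(counts))
  totals <- rep_len(as.numeric(totals), ncol(counts))
  if (any(lengths <= 0)) stop("feature lengths must be positive")
  if (any(totals <= 0)) stop("library totals must be positive")
  sweep(counts / lengths, 2, totals, "/") * 1e9
}

#' Fold changes with t-tests and BH adjustment
#'
#' Per-feature log2 fold change of mutant over wild-type mean levels (with
#' a pseudo-count for stability), two-sample two-tailed t-test across
#' replicates (Welch by default; set `var_equal = TRUE` for the pooled
#' form), and Benjamini-Hochberg adjustment across all features of the
#' table (one modality).
#'
#' @param wt,mut Numeric matrices of per-replicate levels
#'   (features x replicates), same rownames/order.
#' @param pseudo Pseudo-count added to both means before the log ratio.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @param modality Label stored in the `modality` column
#'   (e.g. "RNA", "ChIP", "contact").
#' @return data.frame with columns `id`, `modality`, `mean_wt`, `mean_mut`,
#'   `log2fc`, `p`, `padj`, `p_defined`. With fewer than 2 replicates in
#'   either condition p-values are `NA` and flagged.
#' @export
fold_change <- function(wt, mut, pseudo = 0.01, var_equal = FALSE,
                        modality = NA_character_) {
  wt <- as.matrix(wt); mut <- as.matrix(mut)
  if (nrow(wt) != nrow(mut)) stop("wt and mut must have the same features")
  ids <- rownames(wt)
  if (is.null(ids)) ids <- paste0("feature", seq_len(nrow(wt)))
  mean_wt <- rowMeans(wt); mean_mut <- rowMeans(mut)
  log2fc <- log2((mean_mut + pseudo) / (mean_wt + pseudo))
  p_defined <- ncol(wt) >= 2 && ncol(mut) >= 2
  if (!p_defined) {
    warning("fewer than 2 replicates per condition; p-values undefined")
    p <- rep(NA_real_, nrow(wt))
  } else {
    p <- vapply(seq_len(nrow(wt)), function(i) {
      a <- wt[i, ]; b <- mut[i, ]
      if (stats::sd(a) == 0 && stats::sd(b) == 0)
        return(if (mean(a) == mean(b)) 1 else 0)
      tryCatch(stats::t.test(b, a, var.equal = var_equal)$p.value,
               error = function(e) NA_real_)
    }, numeric(1))
  }
  data.frame(id = ids, modality = modality, mean_wt = mean_wt,
             mean_mut = mean_mut, log2fc = log2fc, p = p,
             padj = stats::p.adjust(p, method = "BH"),
             p_defined = p_defined,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call differentially expressed genes
#'
#' Strict thresholds, as conventionally printed: `|log2FC| > lfc_threshold`
#' and `padj < padj_threshold` (boundary values are excluded).
#'
#' With only a handful of replicates a per-gene t-test has little power
#' after genome-wide BH adjustment (that is what shrinkage-based callers
#' buy); `p_column = "p"` selects on the unadjusted p-value instead, a
#' documented low-replicate mode used by the pipeline's enrichment-scan
#' stage.
#'
#' @param table A fold-change table from [fold_change()].
#' @param lfc_threshold Absolute log2 fold-change threshold.
#' @param padj_threshold Threshold applied to `p_column`.
#' @param p_column `"padj"` (default, BH-adjusted) or `"p"` (unadjusted).
#' @return data.frame of class `deg_set` with columns `id`, `log2fc`,
#'   `padj`, `direction` ("up"/"down"); thresholds stored as attributes.
#' @export
call_degs <- function(table, lfc_threshold = 0.5, padj_threshold = 0.05,
                      p_column = c("padj", "p")) {
  p_column <- match.arg(p_column)
  pv <- table[[p_column]]
  keep <- !is.na(pv) & abs(table$log2fc) > lfc_threshold &
    pv < padj_threshold
  out <- data.frame(id = table$id[keep], log2fc = table$log2fc[keep],
                    padj = table$padj[keep],
                    direction = ifelse(table$log2fc[keep] > 0, "up", "down"),
                    stringsAsFactors = FALSE)
  attr(out, "lfc_threshold") <- lfc_threshold
  attr(out, "padj_threshold") <- padj_threshold
  attr(out, "p_column") <- p_column
  class(out) <- c("deg_set", "data.frame")
  out
}

#' Peak-level enrichment (FPKM-style)
#'
#' Same normalization as [compute_fpkm()] with peak length in place of
#' gene length: `enrichment = counts * 1e9 / (peak_length * total)`.
#'
#' @param peaks data.frame with a `length` column (bp), or numeric lengths.
#' @param counts Matrix of per-peak read counts (peaks x samples).
#' @param totals Per-sample mapped totals.
#' @return Matrix of per-peak enrichment values.
#' @export
peak_enrichment <- function(peaks, counts, totals) {
  lengths <- if (is.data.frame(peaks)) peaks$length else as.numeric(peaks)
  if (any(lengths <= 0)) stop("zero-length peak")
  compute_fpkm(counts, lengths = lengths, totals = totals)
}

#' Reads-per-million profile
#'
#' Scales a fragment count track (vector, or matrix of tracks in columns)
#' to reads per million: `value * 1e6 / total`. Each non-empty track sums
#' to exactly 1e6.
#'
#' @param counts Numeric vector or matrix of fragment counts.
#' @return RPM values with the shape of the input.
#' @export
rpm_profile <- function(counts) {
  f <- function(v) {
    tot <- sum(v)
    if (tot <= 0) stop("all-zero track has no RPM profile")
    v * 1e6 / tot
  }
  if (is.matrix(counts)) apply(counts, 2, f) else f(counts)
}

#' Per-gene contact levels from per-cluster 4C tracks
#'
#' Converts the 4C component of [simulate_chip_and_4c()] into a
#' genes x samples matrix of contact levels: each track is RPM-normalized
#' ([rpm_profile()]), per-gene values are read off the track of the gene's
#' own cluster via [gene_contact_probability()].
#'
#' @param fourc The `fourc` list of a [simulate_chip_and_4c()] result.
#' @param annotation A `locus_annotation`.
#' @return Numeric matrix (clustered genes x samples) of RPM contact
#'   levels.
#' @export
fourc_gene_levels <- function(fourc, annotation) {
  genes <- annotation$genes
  cl <- genes[genes$cluster != "background", , drop = FALSE]
  out <- matrix(NA_real_, nrow(cl), nrow(fourc$samples),
                dimnames = list(cl$id, fourc$samples$sample))
  for (k in names(fourc$counts)) {
    rpm <- rpm_profile(fourc$counts[[k]])
    sel <- cl$cluster == k
    for (j in seq_len(ncol(rpm))) {
      v <- gene_contact_probability(
        data.frame(start = fourc$fragments$start,
                   end = fourc$fragments$end, value = rpm[, j]),
        annotation)
      out[sel, j] <- v[cl$id[sel]]
    }
  }
  out
}

#' Per-gene contact values from a matrix row or 4C track
#'
#' Assigns contact signal to each clustered gene by summing the normalized
#' signal over the bins (virtual-4C row of a contact matrix) or fragments
#' (4C track) that overlap the gene's variable-exon interval (any overlap
#' of at least 1 bp, half-open arithmetic), anchored at a named enhancer
#' viewpoint.
#'
#' @param x Either a `contact_matrix` (the viewpoint row is extracted) or a
#'   data.frame track with columns `start`, `end`, `value` (e.g. an RPM
#'   profile with fragment coordinates).
#' @param annotation A `locus_annotation`.
#' @param anchor Enhancer element name used as the viewpoint (matrix route
#'   only; must fall inside the matrix).
#' @return Named numeric vector, one value per clustered gene.
#' @export
gene_contact_probability <- function(x, annotation, anchor = "HS5-1bL") {
  genes <- annotation$genes
  genes <- genes[genes$cluster != "background", , drop = FALSE]
  if (inherits(x, "contact_matrix")) {
    enh <- annotation$enhancers
    if (!anchor %in% enh$name) stop("unknown anchor element: ", anchor)
    mid <- with(enh[enh$name == anchor, ], (start + end) / 2)
    bin <- floor((mid - x$start) / x$bin_size) + 1
    n <- nrow(x$counts)
    if (bin < 1 || bin > n) stop("anchor falls outside the contact matrix")
    track <- data.frame(
      start = x$start + (seq_len(n) - 1) * x$bin_size,
      end = x$start + seq_len(n) * x$bin_size,
      value = as.numeric(x$counts[bin, ]))
  } else {
    track <- x
    if (!all(c("start", "end", "value") %in% names(track)))
      stop("track must have columns start, end, value")
  }
  frag <- IRanges::IRanges(start = as.integer(track$start) + 1L,
                           end = as.integer(track$end))
  exon <- IRanges::IRanges(start = as.integer(genes$exon_start) + 1L,
                           end = as.integer(genes$exon_end))
  hits <- IRanges::findOverlaps(exon, frag, minoverlap = 1L)
  val <- rep(0, nrow(genes))
  agg <- tapply(track$value[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits), sum)
  val[as.integer(names(agg))] <- agg
  names(val) <- genes$id
  val
}
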