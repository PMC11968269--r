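# Evaluate expr with a temporarily seeded RNG, restoring global state after.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  expr
}

#' Simulate replicate expression counts for both conditions
#'
#' Draws negative-binomial counts for every gene under wild-type and mutant
#' conditions. Clustered genes respond to the mutation through the contact
#' model: `mu_mut = mu_wt * contact_ratio(d)^eta`, where `d` is the gene's
#' promoter-enhancer distance, so with the background contact term disabled
#' the expected log2 fold change of a clustered gene is
#' `-eta * d * (1/lambda_mut - 1/lambda_wt) / ln 2`. A configurable
#' fraction of background genes receives planted condition-dependent fold
#' changes (the remainder are condition-independent), providing the
#' genome-wide null/alternative mix for the enrichment scan.
#'
#' @param annotation A `locus_annotation`.
#' @param params A [processivity_params()].
#' @param nb_dispersion Negative-binomial dispersion (1/size); must be > 0.
#' @param depth Nominal library size (mapped reads) per sample; must be > 0.
#' @param replicates Replicates per condition (default 3).
#' @param seed RNG seed.
#' @param baseline_fpkm Baseline expression of clustered genes (FPKM).
#' @param background_meanlog,background_sdlog Log-normal parameters of
#'   background-gene baseline FPKM.
#' @param background_de_fraction Fraction of background genes given planted
#'   fold changes.
#' @param background_de_sd SD of planted background log2 fold changes.
#' @return Object of class `count_matrix`: list with `counts`
#'   (genes x samples, integer), `samples` (data.frame: sample, condition,
#'   replicate), `lengths`, `library_sizes`, `true_log2fc` (expected
#'   log2FC per gene under the generator), `params`.
#' @export
simulate_expression <- function(annotation, params = processivity_params(),
                                nb_dispersion = 0.05, depth = 2e7,
                                replicates = 3L, seed = 1234,
                                baseline_fpkm = 50,
                                background_meanlog = log(30),
                                background_sdlog = 1,
                                background_de_fraction = 0.1,
                                background_de_sd = 1) {
  if (depth <= 0) stop("depth must be positive")
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  genes <- annotation$genes
  d <- promoter_enhancer_distance(annotation)
  .with_seed(seed, {
    is_bg <- genes$cluster == "background"
    mu_fpkm <- ifelse(is_bg,
                      stats::rlnorm(nrow(genes), background_meanlog,
                                    background_sdlog),
                      baseline_fpkm)
    ratio <- rep(1, nrow(genes))
    cl <- !is_bg
    ratio[cl] <- contact_ratio(d[genes$id[cl]], params) ^ params$eta
    if (any(is_bg) && background_de_fraction > 0) {
      n_de <- round(sum(is_bg) * background_de_fraction)
      de_idx <- sample(which(is_bg), n_de)
      ratio[de_idx] <- 2 ^ stats::rnorm(n_de, 0, background_de_sd)
    }
    mu_wt <- mu_fpkm * (genes$length / 1000) * (depth / 1e6)
    mu_mut <- mu_wt * ratio
    size <- 1 / nb_dispersion
    draw <- function(mu) matrix(
      stats::rnbinom(length(mu) * replicates, mu = rep(mu, replicates),
                     size = size),
      nrow = length(mu), ncol = replicates)
    counts <- cbind(draw(mu_wt), draw(mu_mut))
    rownames(counts) <- genes$id
    samples <- data.frame(
      sample = c(paste0("WT_", seq_len(replicates)),
                 paste0("MUT_", seq_len(replicates))),
      condition = rep(c("wt", "mut"), each = replicates),
      replicate = rep(seq_len(replicates), 2),
      stringsAsFactors = FALSE)
    colnames(counts) <- samples$sample
    structure(list(counts = counts, samples = samples,
                   lengths = stats::setNames(genes$length, genes$id),
                   library_sizes = stats::setNames(
                     rep(depth, nrow(samples)), samples$sample),
                   true_log2fc = stats::setNames(log2(ratio), genes$id),
                   params = params),
              class = "count_matrix")
  })
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("Simulated count matrix:", nrow(x$counts), "genes x",
      ncol(x$counts), "samples\n")
  cat("  conditions:", paste(unique(x$samples$condition), collapse = "/"),
      " replicates:", max(x$samples$replicate), "\n")
  invisible(x)
}

#' Constructor for binned contact matrices
#'
#' @param counts Square symmetric matrix of non-negative counts.
#' @param bin_size Bin width in bp.
#' @param chrom Chromosome name.
#' @param start Genomic start (bp) of the first bin (0-based).
#' @param weights Optional balancing weights (NA at masked bins).
#' @param boundaries Optional planted domain-boundary bin indices
#'   (1-based, recorded as ground truth by the simulators).
#' @return Object of class `contact_matrix`.
#' @export
contact_matrix <- function(counts, bin_size, chrom = "chrS", start = 0,
                           weights = NULL, boundaries = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("contact matrix must be square")
  if (any(counts < 0)) stop("contact counts must be non-negative")
  if (max(abs(counts - t(counts))) > 1e-8 * max(1, max(counts)))
    stop("contact matrix must be symmetric")
  if (bin_size <= 0) stop("bin_size must be positive")
  structure(list(counts = counts, bin_size = bin_size, chrom = chrom,
                 start = start, weights = weights, boundaries = boundaries),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  n <- nrow(x$counts)
  cat(sprintf("Contact matrix: %d x %d bins of %g bp (%s:%.0f-%.0f)\n",
              n, n, x$bin_size, x$chrom, x$start,
              x$start + n * x$bin_size))
  cat(sprintf("  cis total: %.4g%s\n", cis_total(x),
              if (!is.null(x$weights)) "; balanced" else ""))
  invisible(x)
}

# Total cis contact count: each unordered bin pair counted once.
cis_total <- function(mat) {
  m <- mat$counts
  sum(m[upper.tri(m, diag = TRUE)])
}

# Expected contact surface shared by the matrix simulators: power-law
# distance decay times a within-domain block elevation.
.expected_block_surface <- function(n_bins, boundaries, decay_exponent,
                                    domain_boost) {
  s <- abs(outer(seq_len(n_bins), seq_len(n_bins), "-"))
  e <- (s + 1) ^ (-decay_exponent)
  dom <- findInterval(seq_len(n_bins), c(1, boundaries))
  e * ifelse(outer(dom, dom, "=="), domain_boost, 1)
}

#' Simulate a domain-structured contact matrix benchmark
#'
#' Generates a symmetric Poisson-sampled contact matrix with a power-law
#' distance decay and planted topological-domain blocks (within-domain
#' contacts elevated by `domain_boost`). The planted boundary positions are
#' recorded in the returned object as ground truth for boundary-recovery
#' benchmarks. The default 40-kb bins put the default 2-Mb directionality
#' window at 50 bins, the classic domain-calling scale.
#'
#' @param n_bins Number of bins.
#' @param bin_size Bin width (bp).
#' @param boundaries Interior domain-boundary bin indices (1-based: bin `b`
#'   is the first bin of a new domain). Default: 8 evenly spaced interior
#'   boundaries.
#' @param cis_depth Target total cis contacts (unordered pairs).
#' @param domain_boost Within-domain contact elevation factor.
#' @param decay_exponent Distance power-law exponent.
#' @param seed RNG seed.
#' @param chrom,start Coordinates of the binned region.
#' @return A [contact_matrix()] with `boundaries` set to the planted truth.
#' @export
simulate_tad_matrix <- function(n_bins = 500, bin_size = 40000,
                                boundaries = NULL, cis_depth = 2e6,
                                domain_boost = 3, decay_exponent = 1,
                                seed = 1, chrom = "chrS", start = 0) {
  if (bin_size <= 0) stop("bin_size must be positive")
  if (is.null(boundaries))
    boundaries <- round(seq(0, n_bins, length.out = 10))[2:9]
  e <- .expected_block_surface(n_bins, boundaries, decay_exponent,
                               domain_boost)
  e <- e * cis_depth / sum(e[upper.tri(e, diag = TRUE)])
  .with_seed(seed, {
    up <- upper.tri(e, diag = TRUE)
    m <- matrix(0, n_bins, n_bins)
    m[up] <- stats::rpois(sum(up), e[up])
    m <- m + t(m) - diag(diag(m))
    contact_matrix(m, bin_size, chrom = chrom, start = start,
                   boundaries = boundaries)
  })
}

#' Simulate the locus contact matrix
#'
#' Contact matrix over the clustered locus (plus flanks) at close-up
#' resolution: power-law distance decay, planted domain blocks at the
#' cluster boundaries, and an extrusion-driven enhancer contact term added
#' on the rows/columns of every enhancer element, evaluated with the
#' condition's processivity `lambda` (see [enhancer_contact()]). Counts are
#' Poisson-sampled and symmetric; the expected total cis count equals
#' `cis_depth`.
#'
#' @param annotation A `locus_annotation`.
#' @param params A [processivity_params()].
#' @param condition `"wt"` or `"mut"`.
#' @param bin_size Bin width (bp); default 10 kb (close-up resolution).
#' @param cis_depth Target total cis contacts.
#' @param seed RNG seed.
#' @param flank Flanking span (bp) added on each side of the locus.
#' @param domain_boost Within-domain elevation factor.
#' @param decay_exponent Distance power-law exponent.
#' @param enhancer_strength Weight of the enhancer contact term relative
#'   to the local background.
#' @return A [contact_matrix()]; `boundaries` records the planted domain
#'   boundaries (bins of the locus start, inter-cluster gaps, enhancer
#'   block start and locus end).
#' @export
simulate_contact_matrix <- function(annotation,
                                    params = processivity_params(),
                                    condition = c("wt", "mut"),
                                    bin_size = 10000, cis_depth = 2e6,
                                    seed = 1, flank = 100000,
                                    domain_boost = 2, decay_exponent = 1,
                                    enhancer_strength = 5) {
  condition <- match.arg(condition)
  if (bin_size <= 0) stop("bin_size must be positive")
  genes <- annotation$genes
  cl <- genes[genes$cluster != "background", , drop = FALSE]
  enh <- annotation$enhancers
  region_start <- max(0, min(cl$anchor) - flank)
  region_end <- max(enh$end) + flank
  n_bins <- ceiling((region_end - region_start) / bin_size)
  to_bin <- function(pos) floor((pos - region_start) / bin_size) + 1
  # planted boundaries: locus start, cluster transitions, enhancer block, end
  cluster_starts <- vapply(c("beta", "gamma"), function(k)
    min(cl$anchor[cl$cluster == k]), numeric(1))
  boundaries <- sort(unique(to_bin(c(min(cl$anchor), cluster_starts,
                                     min(enh$start),
                                     max(enh$end)))))
  boundaries <- boundaries[boundaries > 1 & boundaries <= n_bins]
  e <- .expected_block_surface(n_bins, boundaries, decay_exponent,
                               domain_boost)
  enh_bins <- unique(to_bin((enh$start + enh$end) / 2))
  base_scale <- mean(e)
  for (b in enh_bins) {
    d_bp <- abs(seq_len(n_bins) - b) * bin_size
    add <- enhancer_strength * base_scale *
      enhancer_contact(d_bp, params, condition)
    e[b, ] <- e[b, ] + add
    e[, b] <- e[, b] + add
  }
  e <- e * cis_depth / sum(e[upper.tri(e, diag = TRUE)])
  .with_seed(seed, {
    up <- upper.tri(e, diag = TRUE)
    m <- matrix(0, n_bins, n_bins)
    m[up] <- stats::rpois(sum(up), e[up])
    m <- m + t(m) - diag(diag(m))
    contact_matrix(m, bin_size, chrom = annotation$genome$chrom,
                   start = region_start, boundaries = boundaries)
  })
}

#' Simulate ChIP peak counts and 4C fragment tracks
#'
#' ChIP: one peak per clustered gene promoter plus one per enhancer
#' element. Mutant intensity at CTCF-site peaks scales with the contact
#' ratio at the peak's promoter-enhancer distance; elements without CTCF
#' sites (the HS7/HS7L analogs) are condition-independent. 4C: one track
#' per cluster, with the viewpoint at the reference point of the cluster's
#' assigned enhancer element set (the enhancer-promoter effect is a
#' cluster-level property of the assigned set); per-fragment Poisson counts
#' have expectation proportional to the contact model evaluated at the
#' distance from the viewpoint.
#'
#' @param annotation A `locus_annotation`.
#' @param params A [processivity_params()].
#' @param seed RNG seed.
#' @param replicates Replicates per condition.
#' @param baseline_reads Expected reads per promoter peak per replicate
#'   (enhancer peaks get three times this).
#' @param anchors Named list of enhancer element sets used as 4C
#'   viewpoints, one per cluster; defaults to each cluster's assigned set
#'   ([assign_enhancer()]). Unknown element names are an error.
#' @param frag_size 4C fragment width (bp).
#' @param flank Span (bp) added around the locus for the 4C track.
#' @param window_span Half-width (bp) of the symmetric window around each
#'   viewpoint in which that track carries signal; reads are normalized
#'   within this window (fragments outside it get zero expectation), so
#'   every track sees the same distance window regardless of where its
#'   viewpoint sits.
#' @param total_4c Expected total reads per 4C track.
#' @return List with `peaks` (list: `table`, `counts`, `samples`) and
#'   `fourc` (list: `fragments`, `counts` — a named list of per-cluster
#'   matrices, `viewpoints`, `samples`).
#' @export
simulate_chip_and_4c <- function(annotation, params = processivity_params(),
                                 seed = 1, replicates = 3L,
                                 baseline_reads = 2000, anchors = NULL,
                                 frag_size = 1000, flank = 50000,
                                 window_span = 1.25e6, total_4c = 5e6) {
  enh <- annotation$enhancers
  if (is.null(anchors)) {
    anchors <- assign_enhancer(c("alpha", "beta", "gamma"))
    names(anchors) <- c("alpha", "beta", "gamma")
  }
  bad <- setdiff(unlist(anchors), enh$name)
  if (length(bad)) stop("unknown anchor element(s): ",
                        paste(bad, collapse = ", "))
  genes <- annotation$genes
  cl <- genes[genes$cluster != "background", , drop = FALSE]
  d <- promoter_enhancer_distance(annotation)[cl$id]

  no_ctcf <- c("HS7", "HS7L")
  # representative distance for each CTCF-bearing enhancer: median distance
  # of the cluster(s) it serves
  enh_cluster <- c("HS5-1" = "alpha", "HS5-1bL" = "gamma",
                   "HS18-20" = "beta", "HS21" = "beta", "HS22" = "beta")
  enh_d <- vapply(enh$name, function(nm) {
    if (nm %in% no_ctcf) return(NA_real_)
    stats::median(d[cl$cluster == enh_cluster[[nm]]])
  }, numeric(1))

  peak_tab <- rbind(
    data.frame(peak = paste0(cl$id, "_prom"), kind = "promoter",
               target = cl$id, cluster = cl$cluster, chrom = cl$chrom,
               start = cl$anchor - 500, end = cl$anchor + 500,
               has_ctcf = TRUE, distance = unname(d),
               stringsAsFactors = FALSE),
    data.frame(peak = enh$name, kind = "enhancer", target = enh$name,
               cluster = NA_character_, chrom = enh$chrom,
               start = enh$start, end = enh$end,
               has_ctcf = !(enh$name %in% no_ctcf),
               distance = unname(enh_d), stringsAsFactors = FALSE))
  peak_tab$length <- peak_tab$end - peak_tab$start
  base <- ifelse(peak_tab$kind == "promoter", baseline_reads,
                 3 * baseline_reads)
  ratio <- rep(1, nrow(peak_tab))
  scaled <- peak_tab$has_ctcf & is.finite(peak_tab$distance)
  ratio[scaled] <- contact_ratio(peak_tab$distance[scaled], params)

  viewpoints <- vapply(anchors, enhancer_reference_point,
                       numeric(1), annotation = annotation)
  lo <- max(0, min(min(cl$anchor) - flank, min(viewpoints) - window_span))
  hi <- min(annotation$genome$length,
            max(max(enh$end) + flank, max(viewpoints) + window_span))
  frag_start <- seq(frag_size * floor(lo / frag_size), hi, by = frag_size)
  fragments <- data.frame(chrom = annotation$genome$chrom,
                          start = frag_start, end = frag_start + frag_size,
                          stringsAsFactors = FALSE)

  samples <- data.frame(
    sample = c(paste0("WT_", seq_len(replicates)),
               paste0("MUT_", seq_len(replicates))),
    condition = rep(c("wt", "mut"), each = replicates),
    replicate = rep(seq_len(replicates), 2), stringsAsFactors = FALSE)

  .with_seed(seed, {
    draw <- function(mu, n) matrix(stats::rpois(length(mu) * n,
                                                rep(mu, n)),
                                   nrow = length(mu), ncol = n)
    peak_counts <- cbind(draw(base, replicates),
                         draw(base * ratio, replicates))
    rownames(peak_counts) <- peak_tab$peak
    colnames(peak_counts) <- samples$sample
    fourc_counts <- lapply(viewpoints, function(vp) {
      d_frag <- abs((fragments$start + fragments$end) / 2 - vp)
      inside <- d_frag <= window_span
      e_wt <- enhancer_contact(d_frag, params, "wt") * inside
      e_mut <- enhancer_contact(d_frag, params, "mut") * inside
      m <- cbind(draw(e_wt * total_4c / sum(e_wt), replicates),
                 draw(e_mut * total_4c / sum(e_mut), replicates))
      colnames(m) <- samples$sample
      m
    })
    list(peaks = list(table = peak_tab, counts = peak_counts,
                      samples = samples),
         fourc = list(fragments = fragments, counts = fourc_counts,
                      viewpoints = viewpoints, samples = samples))
  })
}
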