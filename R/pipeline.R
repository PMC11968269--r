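#' Pipeline run configuration
#'
#' Assembles the full, serializable configuration for [run_pipeline()]:
#' generator settings, per-stage parameters, thresholds and stage toggles.
#' Every threshold used downstream is surfaced here; nothing is hard-coded
#' in the stages. The single root `seed` deterministically spawns one seed
#' per stage.
#'
#' @param seed Root RNG seed.
#' @param locus List of overrides for [locus_config()].
#' @param params List of overrides for [processivity_params()].
#' @param expression List of overrides for [simulate_expression()]
#'   (depth, replicates, nb_dispersion, ...).
#' @param chip4c List of overrides for [simulate_chip_and_4c()].
#' @param contact List of overrides for [simulate_contact_matrix()].
#' @param deg List: `lfc_threshold`, `padj_threshold` for [call_degs()].
#' @param scan List: `width`, `step` for [bin_genome()].
#' @param topology List: `target_depth`, `kr_tol`, `window`, `n_states`.
#' @param stages Named logical vector toggling the five stages.
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(seed = 1234,
                            locus = list(),
                            params = list(),
                            expression = list(),
                            chip4c = list(),
                            contact = list(),
                            deg = list(lfc_threshold = 0.5,
                                       padj_threshold = 0.05,
                                       p_column = "p"),
                            scan = list(width = 1e6, step = NULL),
                            topology = list(target_depth = 1e8,
                                            kr_tol = 1e-8, window = NULL,
                                            n_states = 3),
                            stages = c(simulate = TRUE, quantify = TRUE,
                                       scan = TRUE, distance = TRUE,
                                       topology = TRUE)) {
  cfg <- list(seed = as.integer(seed), locus = locus, params = params,
              expression = expression, chip4c = chip4c, contact = contact,
              deg = deg, scan = scan, topology = topology,
              stages = stages)
  cfg$hash <- .hash_obj(cfg[setdiff(names(cfg), "hash")])
  class(cfg) <- "run_config"
  cfg
}

.hash_obj <- function(x) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

# deterministic per-stage seeds spawned from the root seed
.stage_seed <- function(seed, stage) {
  idx <- match(stage, c("simulate", "quantify", "scan", "distance",
                        "topology"))
  as.integer((as.numeric(seed) * 31 + idx * 10007) %% 2147483647)
}

#' Run the full simulate-quantify-scan-distance-topology pipeline
#'
#' Orchestrates the five stages as one reproducible run. Each stage
#' receives a seed derived deterministically from the root seed and logs
#' it. With an `outdir`, stage outputs are written as plain-text
#' interchange files (BED/TSV/MatrixMarket/bedGraph/JSON) along with a
#' machine-readable `report.json`. A stage that is toggled off leaves its
#' outputs absent; a downstream stage that needs them fails with an error
#' naming the missing stage.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return A list of class `run_report` with per-stage summaries
#'   (DEG counts, top Manhattan bin, fitted slopes, recovered lambda, TAD
#'   count), the config hash, per-stage seeds, and a `results` list with
#'   the in-memory stage objects.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  on_stage <- function(s) isTRUE(config$stages[[s]])
  say <- function(...) if (!quiet) message(...)
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  need <- function(x, stage, from) {
    if (is.null(x))
      stop(sprintf("stage '%s' needs outputs of stage '%s', which is off",
                   stage, from))
    x
  }
  seeds <- stats::setNames(
    vapply(c("simulate", "quantify", "scan", "distance", "topology"),
           function(s) .stage_seed(config$seed, s), integer(1)),
    c("simulate", "quantify", "scan", "distance", "topology"))
  res <- list()
  report <- list(config_hash = config$hash, seed = config$seed,
                 stage_seeds = as.list(seeds),
                 package_version = as.character(
                   utils::packageVersion("cohesinproc")))

  annotation <- do.call(locus_config, config$locus)
  annotation <- build_locus_annotation(annotation)
  params <- do.call(processivity_params, config$params)
  res$annotation <- annotation
  res$params <- params
  report$n_cluster_genes <-
    sum(annotation$genes$cluster != "background")

  if (on_stage("simulate")) {
    say("stage simulate (seed ", seeds[["simulate"]], ")")
    ex_args <- utils::modifyList(
      list(annotation = annotation, params = params,
           seed = seeds[["simulate"]]), config$expression)
    res$expr <- do.call(simulate_expression, ex_args)
    c4_args <- utils::modifyList(
      list(annotation = annotation, params = params,
           seed = seeds[["simulate"]] + 1L), config$chip4c)
    res$chip4c <- do.call(simulate_chip_and_4c, c4_args)
    cm <- function(cond, off) do.call(simulate_contact_matrix,
      utils::modifyList(list(annotation = annotation, params = params,
                             condition = cond,
                             seed = seeds[["simulate"]] + off),
                        config$contact))
    res$matrix_wt <- cm("wt", 2L)
    res$matrix_mut <- cm("mut", 3L)
    if (!is.null(outdir)) {
      write_annotation(annotation, file.path(outdir, "locus"))
      write_counts(res$expr, file.path(outdir, "counts.tsv"))
      write_contact_matrix(res$matrix_wt, file.path(outdir, "matrix_wt"))
      write_contact_matrix(res$matrix_mut, file.path(outdir, "matrix_mut"))
      truth <- list(lambda_wt = params$lambda_wt,
                    lambda_mut = params$lambda_mut, eta = params$eta,
                    planted_boundaries = res$matrix_wt$boundaries,
                    true_log2fc = as.list(res$expr$true_log2fc))
      jsonlite::write_json(truth, file.path(outdir, "ground_truth.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }

  if (on_stage("quantify")) {
    say("stage quantify (seed ", seeds[["quantify"]], ")")
    expr <- need(res$expr, "quantify", "simulate")
    chip4c <- need(res$chip4c, "quantify", "simulate")
    fpkm <- compute_fpkm(expr)
    wt <- expr$samples$condition == "wt"
    res$fc_rna <- fold_change(fpkm[, wt, drop = FALSE],
                              fpkm[, !wt, drop = FALSE],
                              modality = "RNA")
    res$degs <- do.call(call_degs,
                        c(list(table = res$fc_rna), config$deg))
    pk <- chip4c$peaks
    enr <- peak_enrichment(pk$table, pk$counts,
                           totals = colSums(pk$counts))
    pwt <- pk$samples$condition == "wt"
    prom <- pk$table$kind == "promoter"
    fc_chip <- fold_change(enr[prom, pwt, drop = FALSE],
                           enr[prom, !pwt, drop = FALSE],
                           modality = "ChIP")
    fc_chip$id <- pk$table$target[prom]
    res$fc_chip <- fc_chip
    fx <- chip4c$fourc
    levels <- fourc_gene_levels(fx, annotation)
    cwt <- fx$samples$condition == "wt"
    res$fc_contact <- fold_change(levels[, cwt, drop = FALSE],
                                  levels[, !cwt, drop = FALSE],
                                  modality = "contact")
    report$deg_count <- nrow(res$degs)
    report$deg_down <- sum(res$degs$direction == "down")
    report$deg_up <- sum(res$degs$direction == "up")
    if (!is.null(outdir)) {
      for (m in c("fc_rna", "fc_chip", "fc_contact"))
        utils::write.table(res[[m]], file.path(outdir,
                                               paste0(m, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  if (on_stage("scan")) {
    say("stage scan (seed ", seeds[["scan"]], ")")
    degs <- need(res$degs, "scan", "quantify")
    down <- degs$id[degs$direction == "down"]
    genes <- annotation$genes
    hits <- data.frame(chrom = genes$chrom[match(down, genes$id)],
                       pos = genes$anchor[match(down, genes$id)])
    width <- if (is.null(config$scan$width)) 1e6 else config$scan$width
    step <- if (is.null(config$scan$step)) width else config$scan$step
    bins <- bin_genome(annotation$genome, width = width, step = step)
    res$scan <- poisson_scan(count_hits(bins, hits))
    res$manhattan <- manhattan_table(res$scan)
    top <- attr(res$manhattan, "top_bin")
    report$top_bin <- list(chrom = top$chrom, start = top$start,
                           end = top$end, k = top$k, fold = top$fold,
                           log10p = top$log10p)
    if (!is.null(outdir))
      utils::write.table(res$manhattan, file.path(outdir, "scan.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (on_stage("distance")) {
    say("stage distance (seed ", seeds[["distance"]], ")")
    report$distance <- list()
    for (m in c("fc_rna", "fc_chip", "fc_contact")) {
      fc <- need(res[[m]], "distance", "quantify")
      pairs <- make_pairs(fc, annotation)
      fit <- fit_distance_trend(pairs)
      rec <- recover_processivity_delta(fit, lambda_wt = params$lambda_wt,
                                        eta = if (m == "fc_rna")
                                          params$eta else 1)
      res[[paste0("trend_", m)]] <- fit
      res[[paste0("recovery_", m)]] <- rec
      report$distance[[fc$modality[1]]] <-
        list(slope = fit$slope, n = fit$n,
             lambda_mut = rec$lambda_mut,
             delta_inv_lambda = rec$delta_inv_lambda)
    }
    res$contrast <- cluster_contrast(res$fc_rna, annotation,
                                     n_boot = 200)
    report$cluster_ordering <- attr(res$contrast, "ordering")
    if (!is.null(outdir))
      utils::write.table(res$contrast, file.path(outdir, "contrast.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (on_stage("topology")) {
    say("stage topology (seed ", seeds[["topology"]], ")")
    mwt <- need(res$matrix_wt, "topology", "simulate")
    mmut <- need(res$matrix_mut, "topology", "simulate")
    target <- config$topology$target_depth
    if (is.null(target)) target <- 1e8
    nwt <- normalize_depth(mwt, target)
    nmut <- normalize_depth(mmut, target)
    kr_tol <- if (is.null(config$topology$kr_tol)) 1e-8
              else config$topology$kr_tol
    res$balanced_wt <- kr_balance(nwt, tol = kr_tol)
    res$di_wt <- directionality_index(res$balanced_wt,
                                      window = config$topology$window)
    n_states <- if (is.null(config$topology$n_states)) 3
                else config$topology$n_states
    res$hmm_wt <- fit_hmm(res$di_wt, n_states = n_states,
                          seed = seeds[["topology"]])
    res$tads_wt <- call_tads(res$hmm_wt, res$di_wt)
    res$diffmap <- differential_contact_map(nmut, nwt)
    report$tad_count <- nrow(res$tads_wt$domains)
    report$tad_boundaries <- res$tads_wt$boundaries
    if (!is.null(outdir)) {
      write_bedgraph(data.frame(chrom = attr(res$di_wt, "chrom"),
                                start = res$di_wt$start,
                                end = res$di_wt$end,
                                value = res$di_wt$di),
                     file.path(outdir, "di_wt.bedGraph"))
      write_tads_bed(res$tads_wt, file.path(outdir, "tads_wt.bed"),
                     chrom = mwt$chrom)
    }
  }

  report$report_hash <- .hash_obj(report)
  if (!is.null(outdir))
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(c(report, list(results = res)), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run (seed ", x$seed, ", config ", substr(x$config_hash, 1, 8),
      ")\n", sep = "")
  cat("  clustered genes:", x$n_cluster_genes, "\n")
  if (!is.null(x$deg_count))
    cat("  DEGs:", x$deg_count, sprintf("(%d down / %d up)\n",
                                        x$deg_down, x$deg_up))
  if (!is.null(x$top_bin))
    cat(sprintf("  top Manhattan bin: %s:%.0f-%.0f  k=%d fold=%.1f -log10p=%.1f\n",
                x$top_bin$chrom, x$top_bin$start, x$top_bin$end,
                x$top_bin$k, x$top_bin$fold, x$top_bin$log10p))
  if (!is.null(x$distance))
    for (m in names(x$distance))
      cat(sprintf("  %s: slope=%.3g/bp, recovered lambda_mut=%.0f bp\n",
                  m, x$distance[[m]]$slope, x$distance[[m]]$lambda_mut))
  if (!is.null(x$tad_count)) cat("  TADs called:", x$tad_count, "\n")
  invisible(x)
}
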