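test_that("FPKM unit case and scale invariance hold", {
  m <- matrix(10, 1, 1, dimnames = list("g1", "s1"))
  expect_equal(compute_fpkm(m, lengths = 1000, totals = 1e6)[1, 1], 10)
  set.seed(1)
  counts <- matrix(rpois(60, 100), 20, 3,
                   dimnames = list(paste0("g", 1:20), paste0("s", 1:3)))
  len <- sample(500:5000, 20)
  tot <- c(1e6, 2e6, 5e5)
  f1 <- compute_fpkm(counts, len, tot)
  expect_equal(compute_fpkm(counts * 2, len, tot * 2), f1)
  # independent formula evaluation, element by element
  oracle <- counts
  for (i in 1:20) for (j in 1:3)
    oracle[i, j] <- counts[i, j] * 1e9 / (len[i] * tot[j])
  expect_equal(f1, oracle, tolerance = 1e-12)
  expect_error(compute_fpkm(counts, c(0, len[-1]), tot), "positive")
  expect_error(compute_fpkm(counts, len, c(0, tot[-1])), "positive")
})

test_that("fold change handles identity, pseudo-counts and replicate checks", {
  x <- matrix(c(1, 2, 3), 1, 3, dimnames = list("g1", NULL))
  fc <- fold_change(x, x)
  expect_equal(fc$log2fc, 0)
  expect_equal(fc$p, 1)
  fc2 <- fold_change(matrix(c(1, 1), 1), matrix(c(4, 4), 1), pseudo = 0)
  expect_equal(fc2$log2fc, 2)
  expect_warning(fc3 <- fold_change(matrix(1, 2, 1), matrix(2, 2, 1)),
                 "replicates")
  expect_true(all(is.na(fc3$p)))
  expect_false(fc3$p_defined[1])
})

test_that("BH-adjusted p-values never drop below raw p-values", {
  set.seed(3)
  wt <- matrix(rnorm(900, 100, 10), 300)
  mut <- matrix(rnorm(900, 100, 10), 300)
  rownames(wt) <- rownames(mut) <- paste0("g", 1:300)
  fc <- fold_change(wt, mut)
  expect_true(all(fc$padj >= fc$p - 1e-15))
  # BH monotonicity: padj nondecreasing in rank-ordered p
  o <- order(fc$p)
  expect_true(all(diff(fc$padj[o]) >= -1e-15))
})

test_that("t-test type-I error is nominal on its own model", {
  set.seed(11)
  n <- 1000
  wt <- matrix(rnorm(3 * n, 50, 5), n)
  mut <- matrix(rnorm(3 * n, 50, 5), n)
  rownames(wt) <- rownames(mut) <- paste0("g", seq_len(n))
  frac <- mean(fold_change(wt, mut)$p < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / n))
})

test_that("DEG thresholds are strict and both p columns are supported", {
  tab <- data.frame(id = c("a", "b", "c", "d"),
                    log2fc = c(0.5, 0.6, -0.7, -2),
                    p = c(0.01, 0.01, 0.2, 0.01),
                    padj = c(0.04, 0.05, 0.4, 0.01))
  degs <- call_degs(tab)
  expect_equal(degs$id, "d")   # 0.5 and padj 0.05 boundaries excluded
  expect_equal(degs$direction, "down")
  raw <- call_degs(tab, p_column = "p")
  expect_setequal(raw$id, c("b", "d"))
  empty <- call_degs(tab[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("planted strong down-regulation is recovered by the DEG caller", {
  # 28 strongly affected genes among ~2000; pooled t-test + unadjusted p
  # (the documented low-replicate mode)
  set.seed(1901)
  n <- 2058
  mu <- rep(2000, n)
  ratio <- rep(1, n); ratio[1:28] <- 1 / 16
  wt <- matrix(rnbinom(3 * n, mu = mu, size = 20), n)
  mut <- matrix(rnbinom(3 * n, mu = mu * ratio, size = 20), n)
  rownames(wt) <- rownames(mut) <- paste0("g", seq_len(n))
  fc <- fold_change(wt, mut, var_equal = TRUE)
  degs <- call_degs(fc, p_column = "p")
  recovered <- sum(paste0("g", 1:28) %in%
                     degs$id[degs$direction == "down"])
  expect_gte(recovered, 27)
})

test_that("peak enrichment mirrors the FPKM formula", {
  peaks <- data.frame(peak = c("p1", "p2"), length = c(1000, 250))
  counts <- matrix(c(10, 5), 2, 1, dimnames = list(peaks$peak, "s1"))
  enr <- peak_enrichment(peaks, counts, totals = 1e6)
  expect_equal(enr[, 1], c(p1 = 10, p2 = 20))
  expect_error(peak_enrichment(data.frame(length = 0), counts[1, , drop = FALSE],
                               1e6), "zero-length")
})

test_that("RPM tracks are conserved and reject empty input", {
  expect_equal(rpm_profile(c(1, 1, 2)), c(250000, 250000, 500000))
  set.seed(4)
  v <- rpois(200, 30)
  expect_equal(sum(rpm_profile(v)), 1e6)
  expect_equal(rpm_profile(v), v * 1e6 / sum(v))
  m <- cbind(a = rpois(50, 10), b = rpois(50, 40))
  expect_equal(colSums(rpm_profile(m)), c(a = 1e6, b = 1e6))
  expect_error(rpm_profile(rep(0, 5)), "all-zero")
})

test_that("gene contact values sum the signal overlapping each exon", {
  ann <- default_annotation()
  genes <- ann$genes[ann$genes$cluster != "background", ]
  m <- simulate_contact_matrix(ann, seed = 9, cis_depth = 2e5)
  v <- gene_contact_probability(m, ann, anchor = "HS5-1bL")
  expect_equal(length(v), 58)
  # brute-force oracle: viewpoint row, loop over bins per gene
  enh <- ann$enhancers
  mid <- with(enh[enh$name == "HS5-1bL", ], (start + end) / 2)
  row <- m$counts[floor((mid - m$start) / m$bin_size) + 1, ]
  n <- nrow(m$counts)
  oracle <- vapply(seq_len(nrow(genes)), function(i) {
    s <- 0
    for (b in seq_len(n)) {
      b0 <- m$start + (b - 1) * m$bin_size
      if (b0 < genes$exon_end[i] && b0 + m$bin_size > genes$exon_start[i])
        s <- s + row[b]
    }
    s
  }, numeric(1))
  expect_equal(unname(v), oracle)
  # genes with identical intervals get identical values; no overlap gives 0
  tr <- data.frame(start = c(0, 100), end = c(50, 200),
                   value = c(5, 7))
  ann2 <- ann
  ann2$genes <- data.frame(id = c("x", "y", "z"),
                           cluster = "alpha", chrom = "chrS", strand = "+",
                           anchor = c(100, 100, 300),
                           exon_start = c(100, 100, 300),
                           exon_end = c(150, 150, 320), length = 50)
  v2 <- gene_contact_probability(tr, ann2)
  expect_equal(v2[["x"]], v2[["y"]])
  expect_equal(v2[["z"]], 0)
  expect_error(gene_contact_probability(m, ann, anchor = "HS99"),
               "unknown anchor")
  tiny <- contact_matrix(matrix(c(1, 0, 0, 1), 2), bin_size = 1000,
                         start = 0)
  expect_error(gene_contact_probability(tiny, ann, anchor = "HS5-1bL"),
               "outside")
})

test_that("per-cluster 4C levels land on the right genes", {
  ann <- default_annotation()
  c4 <- simulate_chip_and_4c(ann, seed = 2)
  lv <- fourc_gene_levels(c4$fourc, ann)
  expect_equal(nrow(lv), 58)
  expect_true(all(is.finite(lv)))
  expect_equal(colnames(lv), c4$fourc$samples$sample)
})
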