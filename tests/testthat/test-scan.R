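test_that("genome binning tiles chromosomes with remainder handling", {
  b <- bin_genome(c(chr1 = 1e8))
  expect_equal(nrow(b), 100)
  expect_equal(b$end - b$start, rep(1e6, 100))
  b2 <- bin_genome(c(chr1 = 2.5e6))
  expect_equal(b2$end - b2$start, c(1e6, 1e6, 0.5e6))
  expect_error(bin_genome(c(chr1 = 1e6), width = 0), "positive")
  expect_error(bin_genome(c(chr1 = 1e6), step = -1), "positive")
})

test_that("sliding mode places a window every step", {
  b <- bin_genome(c(chr1 = 2e6), width = 1e6, step = 5e5)
  expect_equal(b$start, c(0, 5e5, 1e6, 1.5e6))
  expect_equal(b$end, c(1e6, 1.5e6, 2e6, 2e6))
})

test_that("hit counting uses half-open bins and conserves totals", {
  b <- bin_genome(c(chr1 = 1e7))
  expect_equal(count_hits(b, numeric(0))$k, rep(0L, 10))
  # anchor exactly at a boundary belongs to the bin starting there
  expect_equal(count_hits(b, 2e6)$k[3], 1L)
  expect_equal(count_hits(b, 2e6)$k[2], 0L)
  set.seed(5)
  pos <- runif(302, 0, 1e7)
  expect_equal(sum(count_hits(b, pos)$k), 302L)
  expect_error(count_hits(b, 1e7), "outside")
  expect_error(count_hits(b, data.frame(chrom = "chrX", pos = 1)),
               "unknown chromosome")
})

test_that("Poisson scan reproduces hand-computed tails", {
  # 10 bins; 5 hits: 3 in one bin plus 2 singletons -> lambda = 0.5
  b <- bin_genome(c(chr1 = 1e7))
  b <- count_hits(b, c(100, 200, 300, 2e6, 5e6))
  sc <- poisson_scan(b)
  expect_equal(sc$lambda, rep(0.5, 10))
  expect_equal(sc$p[1], 1 - exp(-0.5) * (1 + 0.5 + 0.125),
               tolerance = 1e-10)
  expect_equal(sc$fold[1], 3 / 0.5)
  expect_true(all(sc$p[sc$k == 0] == 1))
  expect_error(poisson_scan(b[0, ]), "no bins")
})

test_that("log-space tail equals direct summation on random small cases", {
  set.seed(8)
  for (i in 1:200) {
    lambda <- runif(1, 0.01, 5)
    k <- sample(0:40, 1)
    direct <- poisson_tail_direct(k, lambda)
    ours <- exp(ppois(k - 1, lambda, lower.tail = FALSE, log.p = TRUE))
    expect_equal(ours, direct, tolerance = 1e-10)
  }
})

test_that("tail probability decreases strictly in k at fixed lambda", {
  b <- data.frame(chrom = "c", start = 0:40 * 10, end = 1:41 * 10,
                  k = 0:40)
  attr(b, "genome") <- data.frame(chrom = "c", length = 410)
  sc <- poisson_scan(b)
  expect_true(all(diff(log(sc$p)) < 0))
  expect_equal(sc$fold, sc$k / sc$lambda)
})

test_that("denominator restriction rescales the rate", {
  b <- bin_genome(c(chr1 = 1e7))
  b <- count_hits(b, c(100, 200, 2e6))
  sc <- poisson_scan(b, denominator_bins = seq_len(10) <= 5)
  expect_equal(sc$lambda[1], 3 / 5)
})

test_that("Manhattan table ranks by significance with positional ties", {
  b <- bin_genome(c(chr1 = 3e6, chr2 = 2e6))
  b <- count_hits(b, data.frame(chrom = c("chr2", "chr1", "chr1"),
                                pos = c(5e5, 2.2e6, 2.4e6)))
  tab <- manhattan_table(poisson_scan(b))
  expect_equal(tab$rank[tab$chrom == "chr1" & tab$start == 2e6], 1)
  # tied single-hit bins rank in genomic order
  ties <- tab[tab$k == 1, ]
  expect_equal(ties$rank[order(ties$chrom, ties$start)], sort(ties$rank))
  top <- attr(tab, "top_bin")
  expect_equal(top$k, 2L)
  empty <- manhattan_table(poisson_scan(count_hits(
    bin_genome(c(chr1 = 2e6)), numeric(0)))[0, ])
  expect_equal(nrow(empty), 0)
})
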