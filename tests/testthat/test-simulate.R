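test_that("expression simulation is reproducible and validates inputs", {
  ann <- default_annotation()
  a <- simulate_expression(ann, seed = 7)
  b <- simulate_expression(ann, seed = 7)
  expect_identical(a$counts, b$counts)
  expect_false(identical(a$counts, simulate_expression(ann, seed = 8)$counts))
  expect_equal(ncol(a$counts), 6)
  expect_true(all(a$counts >= 0))
  expect_error(simulate_expression(ann, depth = 0), "depth")
  expect_error(simulate_expression(ann, nb_dispersion = 0), "dispersion")
})

test_that("eta = 0 decouples expression from the contact model", {
  ann <- default_annotation()
  ex <- simulate_expression(ann, processivity_params(eta = 0), seed = 1)
  cl <- ann$genes$id[ann$genes$cluster != "background"]
  expect_equal(unname(ex$true_log2fc[cl]), rep(0, 58))
})

test_that("empirical log2FC of clustered genes matches the closed form", {
  ann <- default_annotation()
  p <- params_no_bg()
  n_seeds <- 15
  cl <- ann$genes$cluster != "background"
  d <- promoter_enhancer_distance(ann)[cl]
  truth <- -d * (1 / p$lambda_mut - 1 / p$lambda_wt) / log(2)
  emp <- matrix(NA_real_, sum(cl), n_seeds)
  for (s in seq_len(n_seeds)) {
    ex <- simulate_expression(ann, p, seed = 100 + s)
    fp <- compute_fpkm(ex)
    wt <- ex$samples$condition == "wt"
    emp[, s] <- log2(rowMeans(fp[cl, wt]) / rowMeans(fp[cl, !wt])) * -1
  }
  m <- rowMeans(emp)
  se <- apply(emp, 1, sd) / sqrt(n_seeds)
  expect_gt(cor(m, truth), 0.999)
  # mean deviation across genes is within Monte-Carlo error
  z_mean <- mean(m - truth) / (sqrt(mean(se^2)) / sqrt(sum(cl)))
  expect_lt(abs(z_mean), 4)
})

test_that("locus contact matrix is symmetric with the planted boundaries", {
  ann <- default_annotation()
  m <- simulate_contact_matrix(ann, seed = 3, cis_depth = 5e5)
  expect_identical(m$counts, t(m$counts))
  expect_true(all(m$counts >= 0))
  # planted boundaries: locus start, two cluster transitions, enhancer
  # block, locus end
  expect_equal(length(m$boundaries), 5)
  expect_true(all(diff(m$boundaries) > 0))
  # realized cis depth close to target (Poisson total)
  expect_equal(cis_total(m), 5e5, tolerance = 0.02)
  expect_error(simulate_contact_matrix(ann, bin_size = 0), "bin_size")
})

test_that("benchmark matrix records its planted boundaries", {
  b <- c(50, 120, 300, 422)
  m <- simulate_tad_matrix(n_bins = 450, boundaries = b, seed = 2,
                           cis_depth = 4e5)
  expect_identical(m$boundaries, b)
  expect_identical(m$counts, t(m$counts))
})

test_that("shorter mutant lambda depletes distal enhancer-row contacts", {
  ann <- default_annotation()
  far_sum <- function(cond, s) {
    m <- simulate_contact_matrix(ann, condition = cond, seed = s,
                                 cis_depth = 5e5)
    enh <- ann$enhancers
    b <- unique(floor(((enh$start + enh$end) / 2 - m$start) /
                        m$bin_size) + 1)
    n <- nrow(m$counts)
    far <- abs(outer(b, seq_len(n), "-")) * m$bin_size > 5e5
    sum(m$counts[b, ][far]) / cis_total(m)
  }
  wt <- vapply(1:20, function(s) far_sum("wt", s), numeric(1))
  mut <- vapply(1:20, function(s) far_sum("mut", 1000 + s), numeric(1))
  expect_lt(mean(mut), mean(wt))
  expect_gt(mean(wt) - mean(mut), 2 * sd(wt - mut) / sqrt(20))
})

test_that("ChIP and 4C simulation honors CTCF-free elements and the seed", {
  ann <- default_annotation()
  a <- simulate_chip_and_4c(ann, seed = 5)
  b <- simulate_chip_and_4c(ann, seed = 5)
  expect_identical(a$peaks$counts, b$peaks$counts)
  expect_identical(a$fourc$counts, b$fourc$counts)
  expect_error(simulate_chip_and_4c(ann, anchors = list(alpha = "HS99")),
               "unknown anchor")
  # HS7 analog: no CTCF site, mutant/WT expectation 1 (averaged over seeds)
  ratios <- vapply(1:20, function(s) {
    sim <- simulate_chip_and_4c(ann, seed = s)
    wt <- sim$peaks$samples$condition == "wt"
    i <- which(sim$peaks$table$peak == "HS7")
    mean(sim$peaks$counts[i, !wt]) / mean(sim$peaks$counts[i, wt])
  }, numeric(1))
  expect_equal(mean(ratios), 1, tolerance = 0.02)
})

test_that("beta promoter peaks lose more signal than gamma peaks", {
  ann <- default_annotation()
  contrast <- vapply(1:20, function(s) {
    sim <- simulate_chip_and_4c(ann, seed = s)
    tb <- sim$peaks$table
    wt <- sim$peaks$samples$condition == "wt"
    r <- rowMeans(sim$peaks$counts[, !wt]) /
      rowMeans(sim$peaks$counts[, wt])
    mean(r[tb$kind == "promoter" & tb$cluster == "beta"]) -
      mean(r[tb$kind == "promoter" & tb$cluster == "gamma"])
  }, numeric(1))
  expect_true(all(contrast < 0))
})
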