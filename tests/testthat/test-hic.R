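test_that("depth normalization rescales without changing structure", {
  set.seed(2)
  a <- matrix(rpois(100, 20), 10); a <- a + t(a)
  m <- contact_matrix(a, 1e4)
  total <- sum(a[upper.tri(a, diag = TRUE)])
  n1 <- normalize_depth(m, target = total * 50)
  expect_equal(n1$counts, a * 50)
  expect_equal(normalize_depth(m, target = total)$counts, a)
  # pairwise ratios are preserved
  nz <- a > 0
  expect_equal(n1$counts[nz] / a[nz], rep(50, sum(nz)))
  expect_error(normalize_depth(contact_matrix(matrix(0, 2, 2), 1)),
               "empty")
})

test_that("KR balancing solves the 2x2 case in closed form", {
  b <- kr_balance(contact_matrix(matrix(c(2, 1, 1, 2), 2), 1))
  expect_equal(b$weights, rep(1 / sqrt(3), 2), tolerance = 1e-7)
  expect_equal(b$counts, matrix(c(2, 1, 1, 2) / 3, 2), tolerance = 1e-7)
  expect_equal(rowSums(b$counts), c(1, 1), tolerance = 1e-7)
})

test_that("KR balancing flattens random positive matrices", {
  set.seed(21)
  a <- matrix(runif(200 * 200, 0.1, 2), 200); a <- a + t(a)
  b <- kr_balance(contact_matrix(a, 1))
  rs <- rowSums(b$counts)
  expect_lt(sd(rs) / mean(rs), 1e-6)
  # idempotence: balancing a balanced matrix returns unit weights
  b2 <- kr_balance(b)
  expect_equal(b2$weights, rep(1, 200), tolerance = 1e-5)
  # an already doubly-balanced matrix gets equal weights
  db <- kr_balance(contact_matrix(matrix(c(0.6, 0.4, 0.4, 0.6), 2), 1))
  expect_equal(db$weights[1], db$weights[2], tolerance = 1e-9)
})

test_that("KR masks empty rows and reports them", {
  a <- matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 0), 3)
  b <- kr_balance(contact_matrix(a, 1))
  expect_equal(attr(b, "masked"), 3L)
  expect_true(is.na(b$weights[3]))
  expect_equal(rowSums(b$counts)[1:2], c(1, 1), tolerance = 1e-7)
})

test_that("directionality index matches its defining formula", {
  # middle bin: upstream 10, downstream 20
  a <- matrix(c(0, 10, 0, 10, 0, 20, 0, 20, 0), 3)
  di <- directionality_index(contact_matrix(a, 1e4), window = 1)
  expect_equal(di$di[2], (25 / 15) * 2, tolerance = 1e-12)
  expect_gt(di$di[2], 0)   # downstream-biased
  # symmetric bin gives zero
  s <- matrix(c(0, 5, 0, 5, 0, 5, 0, 5, 0), 3)
  expect_equal(directionality_index(contact_matrix(s, 1e4), 1)$di[2], 0)
  expect_error(directionality_index(contact_matrix(s, 1e4), 0), "window")
})

test_that("mirror-reversing the matrix negates and reverses the DI profile", {
  set.seed(31)
  a <- matrix(rpois(400, 15), 20); a <- a + t(a)
  m <- contact_matrix(a, 1e4)
  mr <- contact_matrix(a[20:1, 20:1], 1e4)
  d1 <- directionality_index(m, window = 4)$di
  d2 <- directionality_index(mr, window = 4)$di
  expect_equal(d2, -rev(d1))
})

test_that("zero-coverage bins yield missing DI, not zero", {
  a <- matrix(5, 4, 4); a[2, ] <- 0; a[, 2] <- 0; diag(a) <- 0
  di <- directionality_index(contact_matrix(a, 1e4), window = 2)
  expect_true(is.na(di$di[2]))
  expect_false(anyNA(di$di[-2]))
})

test_that("differential maps are signed, symmetric and antisymmetric in arguments", {
  set.seed(41)
  a <- matrix(rpois(64, 30), 8); a <- a + t(a)
  b <- matrix(rpois(64, 30), 8); b <- b + t(b)
  ma <- contact_matrix(a, 1e4); mb <- contact_matrix(b, 1e4)
  expect_equal(differential_contact_map(ma, ma)$counts, matrix(0, 8, 8))
  d1 <- differential_contact_map(ma, mb)$counts
  expect_equal(differential_contact_map(mb, ma)$counts, -d1)
  expect_equal(d1, t(d1))
  expect_error(differential_contact_map(ma, contact_matrix(a[1:4, 1:4], 1e4)),
               "shapes")
})

test_that("enhancer contacts drop more in ratio at beta than gamma promoters", {
  ann <- default_annotation()
  worse <- vapply(1:5, function(s) {
    mw <- normalize_depth(simulate_contact_matrix(ann, condition = "wt",
                                                  seed = s), 1e6)
    mm <- normalize_depth(simulate_contact_matrix(ann, condition = "mut",
                                                  seed = 1000 + s), 1e6)
    cl <- ann$genes[ann$genes$cluster != "background", ]
    enh <- ann$enhancers
    tb <- function(p) unique(floor((p - mw$start) / mw$bin_size) + 1)
    eb <- tb((enh$start + enh$end) / 2)
    lr <- function(bins) mean(log2((mm$counts[eb, bins] + 1) /
                                     (mw$counts[eb, bins] + 1)))
    lr(tb(cl$anchor[cl$cluster == "beta"])) <
      lr(tb(cl$anchor[cl$cluster == "gamma"]))
  }, logical(1))
  expect_true(all(worse))
})
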