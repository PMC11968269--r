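test_that("cluster-to-enhancer assignment follows the locus map", {
  expect_equal(assign_enhancer("alpha")[[1]], "HS5-1")
  expect_equal(assign_enhancer("beta")[[1]], c("HS18-20", "HS21", "HS22"))
  expect_equal(assign_enhancer("gamma")[[1]], "HS5-1bL")
  expect_null(assign_enhancer("background")[[1]])
  expect_error(assign_enhancer("delta"), "unknown cluster")
})

test_that("distances run from the anchor to the set midpoint", {
  ann <- list(genes = data.frame(id = c("g1", "g2"), cluster = "alpha",
                                 chrom = "c", strand = "+",
                                 anchor = c(1e6, 1.51e6),
                                 exon_start = c(1e6, 1.51e6),
                                 exon_end = c(1.001e6, 1.511e6),
                                 length = 1000),
              enhancers = data.frame(name = "HS5-1", chrom = "c",
                                     start = 1.48e6, end = 1.52e6))
  d <- promoter_enhancer_distance(ann)
  expect_equal(unname(d["g1"]), 5e5)
  # a gene anchored inside the element: distance to midpoint, below the
  # element half-width
  expect_equal(unname(d["g2"]), 1e4)
  expect_lt(d[["g2"]], (1.52e6 - 1.48e6) / 2)
  expect_error(enhancer_reference_point("HS77", default_annotation()),
               "unknown enhancer")
})

test_that("pair construction joins on gene id and checks duplicates", {
  ann <- default_annotation()
  fc <- rna_fold_change(ann, processivity_params(), seed = 1)
  pairs <- make_pairs(fc, ann)
  expect_equal(nrow(pairs), 58)
  expect_true(all(pairs$distance >= 0))
  expect_warning(empty <- make_pairs(fc[0, ], ann), "missing")
  expect_equal(nrow(empty), 0)
  expect_warning(p2 <- make_pairs(fc[fc$id != "Pcdhb1", ], ann),
                 "missing")
  expect_equal(nrow(p2), 57)
  expect_error(make_pairs(rbind(fc, fc[1, ]), ann), "duplicate")
})

test_that("OLS recovers a noiseless linear trend exactly", {
  d <- seq(1e5, 9e5, length.out = 20)
  pairs <- data.frame(distance = d, log2fc = -2e-6 * d)
  # lm warns that the fit is "essentially perfect" -- that is the point here
  fit <- suppressWarnings(fit_distance_trend(pairs))
  expect_equal(fit$slope, -2e-6, tolerance = 1e-12)
  expect_equal(unname(predict(fit, 5e5)), -1, tolerance = 1e-9)
  flat <- suppressWarnings(
    fit_distance_trend(data.frame(distance = d, log2fc = 1.25)))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_error(fit_distance_trend(pairs[1:2, ]), "at least 3")
  # the confidence interval brackets the estimate
  expect_true(fit$slope_ci[1] <= fit$slope && fit$slope <= fit$slope_ci[2])
})

test_that("trend inversion recovers the planted processivity change", {
  slope <- -(1 / 150000 - 1 / 400000) / log(2)
  rec <- recover_processivity_delta(slope, lambda_wt = 4e5, eta = 1)
  expect_equal(rec$lambda_mut, 150000, tolerance = 1e-9)
  expect_true(rec$consistent)
  null <- recover_processivity_delta(0)
  expect_equal(null$delta_inv_lambda, 0)
  expect_equal(null$lambda_mut, null$lambda_wt)
  # a steep positive slope implies an impossible (negative) rate
  bad <- recover_processivity_delta(1e-5, lambda_wt = 4e5)
  expect_false(bad$consistent)
  expect_true(is.na(bad$lambda_mut))
})

test_that("distance_trend behaves like a fitted model object", {
  ann <- default_annotation()
  fc <- rna_fold_change(ann, params_no_bg(), seed = 3)
  fit <- fit_distance_trend(make_pairs(fc, ann))
  expect_s3_class(fit, "distance_trend")
  expect_named(coef(fit), c("(Intercept)", "distance"))
  expect_equal(length(predict(fit)), fit$n)
  expect_output(print(fit), "slope")
  expect_s3_class(summary(fit), "summary.lm")
})

test_that("cluster contrast orders beta below gamma below zero", {
  ann <- default_annotation()
  fc <- rna_fold_change(ann, processivity_params(), seed = 10)
  cc <- cluster_contrast(fc, ann, n_boot = 200)
  m <- setNames(cc$mean, cc$cluster)
  expect_lt(m[["beta"]], m[["gamma"]])
  expect_lt(m[["gamma"]], 0)
  expect_true(all(cc$ci_lo <= cc$mean & cc$mean <= cc$ci_hi))
  expect_error(cluster_contrast(fc, ann, n_boot = 0), "n_boot")
  # identical values collapse the contrast to zero
  fc0 <- fc; fc0$log2fc <- -1
  cc0 <- cluster_contrast(fc0, ann, n_boot = 50)
  expect_equal(diff(range(cc0$mean)), 0)
  expect_warning(cluster_contrast(fc[!grepl("^Pcdhg", fc$id), ], ann,
                                  n_boot = 10), "empty cluster")
})
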