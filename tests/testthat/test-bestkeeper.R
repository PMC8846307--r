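test_that("a constant gene has zero dispersion and unit x-folds", {
  m <- cbind(toy_cq3()$values, gK = rep(21.5, 4))
  d <- bestkeeper_descriptives(cq_matrix(m))
  row <- d[d$gene == "gK", ]
  expect_equal(row$sd_cp, 0)
  expect_equal(row$cv_pct, 0)
  expect_equal(row$min_xfold, -1)
  expect_equal(row$max_xfold, 1)
  expect_equal(row$sd_xfold, 1)
  expect_equal(row$geo_mean, 21.5)
})

test_that("the bundled dataset's descriptive block is reproduced", {
  d <- bestkeeper_descriptives(bovine)
  g <- d[d$gene == "GAPDH", ]
  expect_equal(g$sd_cp, 0.52, tolerance = 0.01 / 0.52)
  expect_equal(g$cv_pct, 2.40, tolerance = 0.01 / 2.4)
  expect_equal(g$min_xfold, -6.06, tolerance = 0.02 / 6.06)
  expect_equal(g$max_xfold, 2.43, tolerance = 0.02 / 2.43)
  # full published row set (10 genes), to printed rounding
  expect_equal(round(d$geo_mean, 2),
               c(21.68, 19.66, 17.64, 20.31, 26.09, 24.72, 27.85, 18.16,
                 19.34, 22.20))
  expect_equal(round(d$ar_mean, 2),
               c(21.69, 19.68, 17.67, 20.33, 26.19, 24.77, 27.86, 18.18,
                 19.35, 22.27))
  expect_equal(round(d$sd_cp, 2),
               c(0.52, 0.62, 0.77, 0.58, 2.08, 1.03, 0.55, 0.63, 0.55,
                 1.29))
  expect_equal(round(d$cv_pct, 2),
               c(2.40, 3.15, 4.34, 2.85, 7.93, 4.18, 1.97, 3.46, 2.85,
                 5.81))
  expect_equal(round(d$min_xfold, 2),
               c(-6.06, -6.18, -4.86, -5.67, -23.84, -9.14, -7.87, -5.56,
                 -6.09, -16.89))
  expect_equal(round(d$max_xfold, 2),
               c(2.43, 3.74, 3.20, 4.25, 17.08, 29.82, 3.39, 4.37, 2.23,
                 37.85))
  expect_equal(round(d$sd_xfold, 2),
               c(1.44, 1.54, 1.70, 1.50, 4.22, 2.05, 1.46, 1.55, 1.47,
                 2.45))
  expect_setequal(d$gene[!d$acceptable], c("HPRT1", "ACTB", "UXT"))
})

test_that("dispersion invariants hold on arbitrary inputs", {
  d <- bestkeeper_descriptives(bovine)
  # geometric mean <= arithmetic mean, both within [min, max]
  expect_true(all(d$geo_mean <= d$ar_mean))
  expect_true(all(d$geo_mean >= d$min & d$ar_mean <= d$max))
  # mean absolute deviation never exceeds the classical SD
  expect_true(all(d$sd_cp <= apply(bovine$values, 2, sd)))
  # x-fold consistency: span factorizes through the geometric mean
  expect_equal(abs(d$min_xfold) * d$max_xfold, 2 ^ (d$max - d$min))
  # shift invariance of sd_cp; means track the shift
  shifted <- bovine$values
  shifted[, "RPS9"] <- shifted[, "RPS9"] + 3
  d2 <- bestkeeper_descriptives(cq_matrix(shifted,
                                          as.character(bovine$group)))
  expect_equal(d2$sd_cp, d$sd_cp)
  expect_equal(d2$ar_mean[d2$gene == "RPS9"],
               d$ar_mean[d$gene == "RPS9"] + 3)
  # brute-force loop equals the vectorized sd_cp
  brute <- sapply(colnames(bovine$values), function(g) {
    x <- bovine$values[, g]; mean(abs(x - mean(x)))
  })
  expect_equal(setNames(d$sd_cp, d$gene), brute, tolerance = 1e-12)
})

test_that("pairwise correlations use the t-distribution with a p floor", {
  pc <- pairwise_correlations(bovine)
  expect_equal(pc$r["GAPDH", "RPL4"], 0.861, tolerance = 0.005 / 0.861)
  expect_equal(diag(pc$r), rep(1, 10), ignore_attr = TRUE)
  # matches cor.test on an arbitrary pair
  ct <- cor.test(bovine$values[, "HPRT1"], bovine$values[, "EEF1A1"])
  expect_equal(pc$r["HPRT1", "EEF1A1"], unname(ct$estimate))
  expect_equal(pc$p_exact["HPRT1", "EEF1A1"], ct$p.value)
  expect_true(all(pc$p >= 0.001, na.rm = TRUE))
  # anti-correlated toy columns
  m <- matrix(c(21, 22, 23, 23, 22, 21, 20, 21, 22), 3,
              dimnames = list(paste0("s", 1:3), c("gA", "gB", "gC")))
  pc2 <- pairwise_correlations(cq_matrix(m))
  expect_equal(pc2$r["gA", "gB"], -1)
  # zero-variance gene -> NA with warning
  m2 <- cbind(m, gK = rep(20, 3))
  expect_warning(pc3 <- pairwise_correlations(cq_matrix(m2)),
                 "zero-variance")
  expect_true(all(is.na(pc3$r[, "gK"])))
})

test_that("the BestKeeper index is a per-sample geometric mean of Cq", {
  idx <- bestkeeper_index(bovine)
  expect_length(idx, 30)
  expect_equal(idx, exp(rowMeans(log(bovine$values))))
  expect_equal(bestkeeper_index(bovine, genes = "GAPDH"),
               bovine$values[, "GAPDH"])
  m <- matrix(c(16, 17, 18, 25, 26, 27), 3, 2,
              dimnames = list(paste0("s", 1:3), c("gA", "gB")))
  expect_equal(unname(bestkeeper_index(cq_matrix(m))["s1"]), 20)
  # acceptable-only index drops the sd >= 1 genes
  idx_acc <- bestkeeper_index(bovine, genes = "acceptable")
  keep <- setdiff(colnames(bovine$values), c("HPRT1", "ACTB", "UXT"))
  expect_equal(idx_acc, exp(rowMeans(log(bovine$values[, keep]))))
})

test_that("index correlations reproduce the published values", {
  ic <- index_correlations(bovine)
  expect_equal(ic$r[ic$gene == "RPS9"], 0.901, tolerance = 0.01 / 0.901)
  expect_equal(ic$r[ic$gene == "HPRT1"], 0.640, tolerance = 0.01 / 0.64)
  # all ten published index correlations, to printed rounding
  expect_equal(round(ic$r, 3),
               c(0.849, 0.894, 0.704, 0.901, 0.640, 0.721, 0.795, 0.649,
                 0.890, 0.748))
  # index built from one gene correlates perfectly with it
  one <- index_correlations(bovine,
                            index = bestkeeper_index(bovine,
                                                     genes = "RPS15"))
  expect_equal(one$r[one$gene == "RPS15"], 1)
})
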