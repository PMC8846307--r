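test_that("a perfectly constant expression pattern scores zero everywhere", {
  # all genes identical up to gene-level constants: no noise, no shifts
  m <- outer(rep(0, 6), c(gA = 18, gB = 22, gC = 26), "+") +
    matrix(rep(c(0, 0.5, 1, 0, 0.5, 1), 3), 6, 3)   # shared loading only
  dimnames(m) <- list(paste0("s", 1:6), c("gA", "gB", "gC"))
  rq <- relative_quantities(cq_matrix(m, group = rep(c("x", "y"), each = 3)))
  nf <- normfinder_grouped(rq)
  expect_equal(unname(nf$stability), rep(0, 3))
  expect_equal(unname(nf$gamma2), 0)
  expect_true(all(nf$sigma2 == 0))
  expect_equal(unname(normfinder_ungrouped(rq)$stability), rep(0, 3))
})

test_that("stability is invariant to loading offsets and gene abundance", {
  rq0 <- bovine_rq
  base <- normfinder_grouped(rq0)
  set.seed(7)
  offs <- rnorm(30, sd = 1)
  cq1 <- cq_matrix(bovine$values + offs, as.character(bovine$group))
  nf1 <- normfinder_grouped(relative_quantities(cq1))
  expect_equal(nf1$stability, base$stability)
  expect_equal(nf1$sigma2, base$sigma2)
  expect_equal(nf1$d, base$d)

  shifted <- bovine$values
  shifted[, "B2M"] <- shifted[, "B2M"] + 4
  nf2 <- normfinder_grouped(relative_quantities(
    cq_matrix(shifted, as.character(bovine$group))))
  expect_equal(nf2$stability, base$stability)
})

test_that("grouped and ungrouped estimators agree in structure", {
  # sigma2 from the grouped path with one group's samples equals the
  # ungrouped estimate on that subset
  cold_rq <- relative_quantities(subset_samples(bovine, "cold_arid"))
  u <- normfinder_ungrouped(cold_rq)
  g <- normfinder_grouped(bovine_rq)
  expect_equal(g$sigma2[, "cold_arid"], u$sigma2)
  expect_error(normfinder_grouped(cold_rq), "2 groups")
  expect_error(normfinder_ungrouped(relative_quantities(toy_cq())),
               "3 genes")
})

test_that("intergroup deviations are zero-sum and mirror with two groups", {
  nf <- normfinder_grouped(bovine_rq)
  d <- intergroup_variation(nf)
  expect_equal(dim(d), c(10L, 2L))
  expect_equal(unname(rowSums(d)), rep(0, 10), tolerance = 1e-12)
  expect_equal(d[, 1], -d[, 2])
  expect_error(intergroup_variation(normfinder_ungrouped(bovine_rq)),
               "grouped")
})

test_that("noise SD ratios are recovered from simulated data", {
  # one gene with double the noise of the rest: recovered ratio within 15%
  sds <- rep(0.4, 10); sds[3] <- 0.8
  spec <- cq_sim_spec(c(a = 200), setNames(seq(18, 27, 1), paste0("g", 1:10)),
                      noise_sd = sds, sample_factor_sd = 0.5)
  nf <- normfinder_ungrouped(relative_quantities(simulate_cq(spec,
                                                             seed = 42)))
  ratio <- nf$stability[["g3"]] / mean(nf$stability[-3])
  expect_equal(ratio, 2, tolerance = 0.15)
})

test_that("sigma^2 estimates are nearly unbiased on model data", {
  # n_g = 100 per group, k = 10 genes, 200 replicates: mean bias < 10%
  sds <- seq(0.2, 0.65, length.out = 10)
  spec <- cq_sim_spec(c(a = 100, b = 100),
                      setNames(seq(18, 27, 1), paste0("g", 1:10)),
                      noise_sd = sds, sample_factor_sd = 0.5)
  acc <- matrix(0, 200, 10)
  for (r in 1:200) {
    nf <- normfinder_grouped(relative_quantities(simulate_cq(spec,
                                                             seed = 1000 + r)))
    acc[r, ] <- rowMeans(nf$sigma2)
  }
  bias <- colMeans(acc) / sds ^ 2 - 1
  expect_lt(mean(abs(bias)), 0.10)
})

test_that("a group-shifted gene is flagged as least stable", {
  baseline <- setNames(seq(18, 27, 1), paste0("g", 1:10))
  shift <- matrix(0, 10, 2, dimnames = list(names(baseline), c("a", "b")))
  shift["g7", ] <- c(0.5, -0.5)   # one full cycle between groups
  spec <- cq_sim_spec(c(a = 15, b = 15), baseline, noise_sd = 0.3,
                      group_shift = shift)
  worst <- 0
  n_seeds <- 50
  for (s in seq_len(n_seeds)) {
    nf <- normfinder_grouped(relative_quantities(simulate_cq(spec,
                                                             seed = s)))
    expect_equal(names(which.max(abs(nf$d[, "a"]))), "g7")
    worst <- worst + (names(which.max(nf$stability)) == "g7")
  }
  expect_gt(worst / n_seeds, 0.5)
})

test_that("bundled-data rankings behave as documented", {
  # combined two-environment analysis: RPL4 heads the ranking
  nf <- normfinder_grouped(bovine_rq)
  expect_equal(names(sort(nf$stability))[1], "RPL4")
  # cold-arid subset grouped by breed: ribosomal genes and EEF1A1 lead
  cold <- subset_samples(bovine_pbmc_cq(group = "breed"),
                         c(paste0("LAC", 1:6), paste0("HFX", 1:5),
                           paste0("JYC", 1:4)))
  nfc <- normfinder_grouped(relative_quantities(cold))
  expect_true(all(c("RPS15", "EEF1A1", "RPS9") %in%
                  names(sort(nfc$stability))[1:3]))
})
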