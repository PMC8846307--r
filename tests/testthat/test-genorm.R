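test_that("pairwise variability matches hand-computed SDs", {
  # duplicate column pasted under a new id -> V = 0
  m <- cbind(toy_cq3()$values, gA2 = toy_cq3()$values[, "gA"])
  rq <- relative_quantities(cq_matrix(m))
  expect_equal(pairwise_variability(rq, "gA", "gA2"), 0)
  expect_error(pairwise_variability(rq, "gA", "gA"), "differ")

  # two samples: log2 ratios {0, 2} -> SD = |delta|/sqrt(2) = sqrt(2)
  m2 <- matrix(c(20, 21, 22, 20, 23, 26, 20, 20, 20), nrow = 3,
               dimnames = list(paste0("s", 1:3), c("gA", "gB", "gC")))
  rq2 <- relative_quantities(cq_matrix(m2))
  expect_equal(pairwise_variability(rq2, "gA", "gB", samples = c("s1", "s2")),
               sqrt(2))

  # bundled data: brute-force SD over explicitly listed log2 ratios
  cqv <- bovine$values
  ratios <- log2(2 ^ (-cqv[, "RPS9"]) / 2 ^ (-cqv[, "RPS15"]))
  expect_equal(pairwise_variability(bovine_rq, "RPS9", "RPS15"),
               sd(ratios))
})

test_that("M values equal the mean pairwise SD, cross-checked by brute force", {
  # exactly 2 genes: M_A = M_B = V_AB
  rq <- relative_quantities(toy_cq())
  m2 <- m_values(rq)
  expect_equal(m2[["gA"]], m2[["gB"]])
  expect_equal(m2[["gA"]], pairwise_variability(rq, "gA", "gB"))

  # 3 genes x 4 samples toy vs enumerated pairs
  rq3 <- relative_quantities(toy_cq3())
  expect_equal(m_values(rq3), brute_m(rq3$values))

  # bundled data vs brute force, all 10 genes
  expect_equal(m_values(bovine_rq), brute_m(bovine_rq$values))
  expect_error(m_values(bovine_rq, genes = "GAPDH"), "2 genes")
})

test_that("M is computable from raw Cq differences when E = 2", {
  cqv <- bovine$values
  m_from_cq <- vapply(colnames(cqv), function(j) {
    mean(vapply(setdiff(colnames(cqv), j),
                function(k) sd(cqv[, j] - cqv[, k]), numeric(1)))
  }, numeric(1))
  expect_equal(m_values(bovine_rq), m_from_cq, tolerance = 1e-12)
})

test_that("M and V are invariant to sample order and loading offsets", {
  set.seed(11)
  perm <- sample(nrow(bovine$values))
  cq_perm <- cq_matrix(bovine$values[perm, ],
                       as.character(bovine$group)[perm])
  rq_perm <- relative_quantities(cq_perm)
  expect_equal(m_values(rq_perm), m_values(bovine_rq))

  # per-sample constant (loading difference) across all genes
  offs <- rnorm(nrow(bovine$values), sd = 0.8)
  cq_load <- cq_matrix(bovine$values + offs, as.character(bovine$group))
  rq_load <- relative_quantities(cq_load)
  expect_equal(m_values(rq_load), m_values(bovine_rq))
  v1 <- pairwise_variation_series(bovine_rq)
  v2 <- pairwise_variation_series(rq_load)
  expect_equal(v2$v, v1$v)
})

test_that("stepwise ranking reproduces the bundled dataset's geNorm results", {
  g <- genorm_ranking(bovine_rq)
  expect_setequal(g$final_pair, c("RPS9", "RPS15"))
  expect_equal(unname(g$stability["RPS9"]), 0.464, tolerance = 0.005 / 0.464)
  expect_equal(g$exclusion$excluded[1], "HPRT1")
  expect_equal(g$exclusion$avg_m[1], 1.228, tolerance = 0.005 / 1.228)
  # reported stability decreases monotonically toward the terminal pair
  expect_true(all(diff(g$stability[g$ranking]) >= 0))
  # full reported column, best to worst
  expect_equal(g$ranking[-(1:2)],
               c("RPL4", "GAPDH", "HMBS", "EEF1A1", "B2M", "UXT", "ACTB",
                 "HPRT1"))

  cold <- genorm_ranking(relative_quantities(subset_samples(bovine,
                                                            "cold_arid")))
  expect_setequal(cold$final_pair, c("RPL4", "EEF1A1"))
  expect_equal(unname(cold$stability["RPL4"]), 0.255,
               tolerance = 0.005 / 0.255)
  hot <- genorm_ranking(relative_quantities(subset_samples(bovine,
                                                           "hot_arid")))
  expect_setequal(hot$final_pair, c("HPRT1", "RPS9"))
  expect_equal(unname(hot$stability["RPS9"]), 0.229,
               tolerance = 0.005 / 0.229)
})

test_that("duplicated genes survive to the terminal pair with M = 0", {
  m <- cbind(toy_cq3()$values[, c("gA", "gC")],
             gA2 = toy_cq3()$values[, "gA"])
  g <- genorm_ranking(relative_quantities(cq_matrix(m)))
  expect_setequal(g$final_pair, c("gA", "gA2"))
  expect_equal(unname(g$stability["gA"]), 0)
})

test_that("normalization factors are per-sample geometric means", {
  rq <- relative_quantities(toy_cq())
  # single gene -> its own RQ column
  expect_equal(normalization_factor(rq, "gA"), rq$values[, "gA"])
  # two genes with RQ 1 and 0.25 -> geometric mean 0.5
  m <- matrix(c(20, 21, 22, 22, 21, 20), 3, 2,
              dimnames = list(paste0("s", 1:3), c("gA", "gB")))
  rq2 <- relative_quantities(cq_matrix(m))
  expect_equal(unname(normalization_factor(rq2, c("gA", "gB"))["s1"]), 0.5)
  # bundled top-3 panel: strictly positive, equals exp(mean log)
  nf <- normalization_factor(bovine_rq, c("RPS9", "RPS15", "RPL4"))
  expect_length(nf, 30)
  expect_true(all(nf > 0))
  expect_equal(nf, exp(rowMeans(log(
    bovine_rq$values[, c("RPS9", "RPS15", "RPL4")]))))
})

test_that("pairwise variation series matches published V values and picks n", {
  vs <- pairwise_variation_series(bovine_rq)
  expect_equal(unname(vs$v["V2:3"]), 0.169, tolerance = 0.005 / 0.169)
  expect_equal(unname(vs$v["V3:4"]), 0.116, tolerance = 0.005 / 0.116)
  expect_equal(vs$optimal_n, 3L)
  expect_true(all(vs$v >= 0))
  expect_length(vs$v, 8)

  # identical columns everywhere -> every V is 0, nothing below threshold
  # is impossible here (0 < 0.15), optimal_n = 2
  m <- matrix(rep(c(20, 21, 22, 23), 4), nrow = 4,
              dimnames = list(paste0("s", 1:4), paste0("g", 1:4)))
  vs0 <- pairwise_variation_series(relative_quantities(cq_matrix(m)))
  expect_equal(unname(vs0$v), rep(0, 2))
  expect_equal(vs0$optimal_n, 2L)

  # no V below an impossibly small threshold -> warn, report k
  expect_warning(vs_k <- pairwise_variation_series(bovine_rq,
                                                   threshold = 1e-6),
                 "no V")
  expect_equal(vs_k$optimal_n, 10L)
})

test_that("inflating one gene's noise raises its M in expectation", {
  spec_lo <- cq_sim_spec(c(a = 8, b = 8),
                         baseline_cq = setNames(seq(18, 27, 1),
                                                paste0("g", 1:10)),
                         noise_sd = 0.3)
  worse <- 0
  n_seeds <- 50
  for (s in seq_len(n_seeds)) {
    sd_hi <- rep(0.3, 10); sd_hi[5] <- 0.9
    spec_hi <- cq_sim_spec(c(a = 8, b = 8), spec_lo$baseline_cq,
                           noise_sd = sd_hi)
    m_lo <- m_values(relative_quantities(simulate_cq(spec_lo, seed = s)))
    m_hi <- m_values(relative_quantities(simulate_cq(spec_hi, seed = s)))
    worse <- worse + (m_hi[["g5"]] > m_lo[["g5"]])
  }
  expect_gt(worse / n_seeds, 0.9)
})
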