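# Shared fixtures built in code.

# 3 samples x 2 genes, Cq spaced one cycle apart -> powers-of-two RQ.
toy_cq <- function() {
  m <- matrix(c(20, 21, 22,
                30, 31, 32), nrow = 3,
              dimnames = list(paste0("s", 1:3), c("gA", "gB")))
  cq_matrix(m, group = c("x", "x", "y"))
}

# 4 samples x 3 genes with hand-checkable pairwise SDs.
toy_cq3 <- function() {
  m <- matrix(c(20.0, 21.0, 22.0, 23.0,
                20.5, 21.2, 22.4, 23.1,
                25.0, 26.5, 26.8, 28.2), nrow = 4,
              dimnames = list(paste0("s", 1:4), c("gA", "gB", "gC")))
  cq_matrix(m)
}

bovine <- bovine_pbmc_cq()
bovine_rq <- relative_quantities(bovine)

# Independent brute-force geNorm M: explicit double loop over pairs.
brute_m <- function(values, base = 2) {
  l <- log(values, base)
  genes <- colnames(l)
  vapply(genes, function(j) {
    others <- setdiff(genes, j)
    mean(vapply(others, function(k) stats::sd(l[, j] - l[, k]),
                numeric(1)))
  }, numeric(1))
}
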