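#' Bovine PBMC reference-gene Cq dataset
#'
#' Quantification-cycle values for 10 candidate reference genes (GAPDH,
#' RPL4, EEF1A1, RPS9, HPRT1, UXT, HMBS, B2M, RPS15, ACTB) measured by
#' SYBR-green RT-qPCR in peripheral blood mononuclear cells of 30 cattle:
#' 15 animals from cold-arid high-altitude (hypoxic) populations (6 Ladakhi
#' LAC, 5 Holstein-Friesian-cross HFX, 4 Jersey JYC) and 15 from hot-arid
#' lowland (normoxic) populations (5 Sahiwal SAC, 5 Karan-Fries KFC,
#' 5 Holstein-Friesian HFC). One Cq per animal and gene (duplicate wells
#' pre-averaged). This dataset is the package's benchmark: its published
#' stability rankings are reproduced by [reproduce_benchmarks()].
#'
#' @param group How to label samples: `"environment"` (default; `cold_arid`
#'   vs `hot_arid`, 15 + 15), `"breed"` (the six populations), or `"none"`.
#' @return A [cq_matrix()] with 30 samples and 10 genes.
#' @examples
#' cq <- bovine_pbmc_cq()
#' cq$values["LAC1", "GAPDH"]   # 22.17
#' @export
bovine_pbmc_cq <- function(group = c("environment", "breed", "none")) {
  group <- match.arg(group)
  genes <- c("GAPDH", "RPL4", "EEF1A1", "RPS9", "HPRT1",
             "UXT", "HMBS", "B2M", "RPS15", "ACTB")
  samples <- c(paste0("LAC", 1:6), paste0("HFX", 1:5), paste0("JYC", 1:4),
               paste0("SAC", 1:5), paste0("KFC", 1:5), paste0("HFC", 1:5))
  vals <- c(
    22.17, 21.56, 18.81, 22.40, 30.18, 26.07, 29.44, 19.36, 19.51, 24.35,
    21.87, 20.06, 17.32, 20.15, 28.38, 23.86, 27.99, 18.20, 19.79, 22.88,
    22.08, 19.67, 16.90, 19.98, 27.95, 24.18, 27.63, 18.72, 19.55, 23.52,
    22.30, 20.15, 17.26, 19.87, 28.14, 24.55, 27.64, 18.57, 19.57, 24.66,
    22.53, 19.61, 17.09, 20.04, 28.87, 24.68, 27.59, 18.75, 19.21, 22.64,
    22.07, 19.75, 17.23, 20.41, 29.69, 24.51, 27.79, 17.74, 19.45, 24.90,
    21.52, 19.35, 16.90, 19.73, 27.46, 24.30, 27.80, 17.61, 18.80, 21.33,
    21.16, 19.40, 17.21, 20.13, 27.31, 24.83, 27.94, 17.18, 19.09, 20.65,
    21.64, 19.71, 17.12, 20.07, 27.71, 24.41, 27.77, 17.82, 19.12, 21.16,
    21.66, 19.76, 17.00, 20.13, 28.55, 23.46, 27.81, 17.66, 18.93, 21.71,
    21.90, 19.78, 17.48, 20.08, 27.83, 26.76, 27.92, 17.81, 19.38, 22.36,
    21.71, 19.39, 17.25, 20.13, 28.40, 25.27, 27.77, 17.64, 19.16, 21.82,
    21.41, 20.10, 17.79, 20.59, 27.80, 26.42, 27.87, 17.72, 19.74, 22.03,
    21.44, 19.34, 17.21, 20.53, 27.43, 26.31, 26.89, 17.82, 19.43, 27.44,
    22.24, 20.58, 18.34, 21.14, 28.26, 29.62, 28.56, 18.85, 20.24, 22.93,
    21.60, 20.38, 18.34, 20.40, 24.43, 27.86, 28.21, 18.09, 19.83, 21.60,
    21.87, 20.18, 18.36, 20.63, 24.95, 23.99, 27.97, 18.04, 19.39, 21.09,
    22.96, 20.04, 18.70, 20.73, 24.09, 24.36, 28.57, 18.91, 19.72, 23.71,
    22.49, 20.65, 18.78, 20.84, 24.64, 24.63, 28.68, 18.29, 20.11, 22.49,
    22.23, 20.80, 19.10, 21.00, 24.91, 24.90, 28.90, 18.71, 20.49, 22.04,
    22.07, 19.84, 18.18, 20.73, 24.58, 24.25, 27.81, 18.10, 19.88, 21.79,
    21.63, 19.73, 19.32, 20.77, 24.44, 24.17, 27.51, 17.75, 19.63, 21.18,
    21.45, 19.24, 17.66, 19.89, 23.60, 24.23, 27.31, 17.73, 18.97, 21.20,
    21.39, 18.73, 17.51, 19.92, 23.71, 23.81, 26.99, 17.57, 18.39, 21.41,
    21.74, 19.65, 17.94, 20.65, 24.40, 24.30, 28.04, 17.95, 19.54, 21.51,
    19.47, 17.07, 15.49, 18.01, 21.51, 21.83, 26.62, 15.69, 17.02, 18.73,
    22.44, 20.56, 19.27, 21.35, 25.41, 25.16, 28.58, 20.29, 20.32, 22.72,
    19.08, 17.03, 15.36, 17.81, 21.59, 21.53, 24.87, 17.95, 16.73, 18.12,
    20.76, 18.38, 16.84, 21.11, 24.78, 24.53, 29.61, 20.04, 20.43, 24.27,
    21.95, 19.90, 18.26, 20.73, 24.61, 24.25, 27.72, 18.96, 19.21, 21.78)
  m <- matrix(vals, nrow = 30, ncol = 10, byrow = TRUE,
              dimnames = list(samples, genes))
  g <- switch(group,
    environment = rep(c("cold_arid", "hot_arid"), each = 15L),
    breed = rep(c("LAC", "HFX", "JYC", "SAC", "KFC", "HFC"),
                times = c(6L, 5L, 4L, 5L, 5L, 5L)),
    none = rep("all", 30L))
  cq_matrix(m, group = g)
}

# Previously reported stability values for the bundled bovine PBMC dataset,
# used as regression benchmarks by reproduce_benchmarks().
published_benchmarks <- function() {
  data.frame(
    check = c(
      "genorm_combined_final_pair_M",
      "genorm_combined_first_excluded_M",
      "genorm_combined_V2_3",
      "genorm_combined_V3_4",
      "genorm_cold_final_pair_M",
      "genorm_hot_final_pair_M",
      "bestkeeper_combined_GAPDH_sd",
      "bestkeeper_combined_GAPDH_cv",
      "bestkeeper_combined_GAPDH_min_xfold",
      "bestkeeper_combined_r_GAPDH_RPL4",
      "bestkeeper_combined_index_r_RPS9",
      "bestkeeper_combined_index_r_HPRT1",
      "normfinder_combined_top_stability",
      "reffinder_combined_RPS9",
      "reffinder_combined_HPRT1",
      "efficiency_slope_-3.30",
      "mean_cq_EEF1A1"),
    reference = c(0.464, 1.228, 0.169, 0.116, 0.255, 0.229,
                  0.52, 2.40, -6.06, 0.861, 0.901, 0.640,
                  0.282, 1.41, 10.00, 100.92, 17.66),
    tolerance = c(0.005, 0.005, 0.005, 0.005, 0.005, 0.005,
                  0.01, 0.01, 0.02, 0.005, 0.01, 0.01,
                  0.01, 0.05, 0.05, 0.005, 0.01),
    stringsAsFactors = FALSE)
}
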