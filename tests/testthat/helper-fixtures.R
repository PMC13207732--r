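# Small fixture builders shared across test files.

# Minimal expression matrix with named genes/samples.
make_expr <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), ncol = length(samples),
         dimnames = list(genes, samples), byrow = TRUE)
}

# A tiny hand-aligned cohort: 3 genes x 4 samples plus mutation/metric/
# clinical layers, for IO and container tests.
make_tiny_cohort <- function(cohort_id = "TINY") {
  samples <- paste0("s", 1:4)
  expr <- make_expr(c(1, 2, 3, 4,
                      8, 6, 4, 2,
                      5, 5, 7, 9), c("FOCAL", "GA", "GB"), samples)
  mut <- make_expr(c(1, 0, 1, 0,
                     0, 0, 0, 1), c("TP53", "KRAS"), samples)
  metrics <- data.frame(sample_id = samples,
                        mutation_count = c(10, 20, 5, 40),
                        fga = c(0.1, 0.2, 0.05, 0.6),
                        stringsAsFactors = FALSE)
  clinical <- data.frame(sample_id = samples,
                         t_stage = c("T1", "T2", "T3", "T4"),
                         grade = c("low", "mid", "high", "high"),
                         os_time = c(100, 200, 300, 50),
                         os_event = c(1, 0, 1, 1),
                         pfs_time = c(80, 150, 250, 40),
                         pfs_event = c(1, 1, 0, 1),
                         stringsAsFactors = FALSE)
  CohortDataset(cohort_id, expr, mut, metrics, clinical)
}

# Write a gene x sample matrix in the cBioPortal-style TSV layout.
write_expr_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Independent rank-then-Pearson Spearman oracle.
spearman_oracle <- function(x, y) stats::cor(rank(x), rank(y))

# Normal-equations OLS oracle: beta-hat = (X'X)^-1 X'y, SE from residual MS.
ols_oracle <- function(y, X) {
  X <- cbind(1, X)
  XtX_inv <- solve(t(X) %*% X)
  beta <- XtX_inv %*% t(X) %*% y
  resid <- y - X %*% beta
  s2 <- sum(resid^2) / (length(y) - ncol(X))
  list(beta = as.vector(beta), se = sqrt(diag(XtX_inv) * s2))
}

# Small-cohort parameters for survival/type-I replicate loops.
tiny_survival_params <- function(preset, seed, n = 80, ...) {
  preset_params(preset, seed = seed, n_cohorts = 1L,
                n_samples_per_cohort = n, n_genes = 5L,
                n_planted_coexpressed = 1L, g2m_set_size = 2L,
                n_driver_genes = 2L, n_passenger_genes = 2L, ...)
}
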