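test_that("g2m_score matches hand-computed z-scores and is affine-invariant", {
  # two samples: log2 values A:(1,3), B:(2,6) -> per-gene z = -+0.7071
  expr <- make_expr(c(2^1 - 1, 2^3 - 1,
                      2^2 - 1, 2^6 - 1,
                      5, 5), c("A", "B", "MKI67"), c("s1", "s2"))
  gs <- structure(list(name = "SET", genes = c("A", "B", "MKI67")),
                  class = "GeneSet")
  co <- CohortDataset("Z", expr)
  sc <- g2m_score(co, gs)   # MKI67 excluded by default
  expect_equal(unname(sc$score), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(sc$n_genes_used, 2)
  expect_true("MKI67" %in% sc$excluded_genes)

  # gene-wise positive affine transform on the log2 scale leaves scores alone
  expr2 <- expr
  expr2["A", ] <- 2^(3 * log2(expr["A", ] + 1) + 7) - 1
  sc2 <- g2m_score(CohortDataset("Z", expr2), gs)
  expect_equal(sc2$score, sc$score, tolerance = 1e-10)

  # excluding the whole set is an error; zero-variance genes are dropped
  expect_error(g2m_score(co, gs, exclude = c("A", "B", "MKI67")),
               "no usable genes")
  gs_flat <- structure(list(name = "S", genes = c("A", "MKI67")),
                       class = "GeneSet")
  expect_warning(sc3 <- g2m_score(co, gs_flat, exclude = character(0)),
                 "zero-variance")
  expect_equal(sc3$n_genes_used, 1)
})

test_that("transform_covariates applies the documented transforms", {
  co <- make_tiny_cohort()
  tc <- transform_covariates(co, "FOCAL")
  expect_equal(tc$focal_log2, log2(c(1, 2, 3, 4) + 1))
  expect_equal(tc$log1p_mutation_count, log1p(c(10, 20, 5, 40)))
  expect_equal(tc$fga, c(0.1, 0.2, 0.05, 0.6))
  # log1p(0) = 0 and log2(0 + 1) = 0
  expect_equal(log1p(0), 0)
  co0 <- make_tiny_cohort()
  co0$expression["FOCAL", 1] <- 0
  expect_equal(transform_covariates(co0, "FOCAL")$focal_log2[1], 0)

  # random vectors match the closed form elementwise
  set.seed(12)
  v <- runif(50, 0, 100)
  expr <- matrix(v, nrow = 1, dimnames = list("F", paste0("s", 1:50)))
  mt <- data.frame(sample_id = paste0("s", 1:50),
                   mutation_count = rpois(50, 30), fga = runif(50))
  coh <- CohortDataset("C", expr, metrics = mt)
  tc2 <- transform_covariates(coh, "F", pseudocount = 1)
  expect_equal(tc2$focal_log2, log(v + 1) / log(2), tolerance = 1e-12)
  expect_equal(tc2$log1p_mutation_count, log(1 + mt$mutation_count),
               tolerance = 1e-12)
})

test_that("fit_instability_model is OLS with exact degenerate behaviour", {
  # exact linear relation
  x <- c(1, 2, 3, 4, 5)
  # lm warns "essentially perfect fit" on zero-residual data; expected here
  r <- suppressWarnings(
    fit_instability_model(2 * x, x, stratum = "s", outcome_name = "y"))
  expect_equal(r$terms$beta[r$terms$term == "focal"], 2, tolerance = 1e-12)
  expect_equal(unname(max(abs(r$residuals))), 0, tolerance = 1e-10)

  # perfect collinearity
  expect_error(fit_instability_model(rnorm(20), x <- rnorm(20), x,
                                     stratum = "s"), "singular")
  expect_error(fit_instability_model(1:3, 1:3, stratum = "s"),
               "insufficient")
})

test_that("OLS matches the normal-equations oracle on random instances", {
  set.seed(2024)
  for (i in 1:50) {
    n <- 100
    k <- sample(1:2, 1)
    X <- matrix(rnorm(n * k), n)
    y <- rnorm(n, mean = X %*% runif(k, -2, 2))
    r <- fit_instability_model(y, X[, 1], if (k == 2) X[, 2],
                               stratum = "s")
    o <- ols_oracle(y, X)
    expect_equal(r$terms$beta, o$beta, tolerance = 1e-8)
    expect_equal(r$terms$se, o$se, tolerance = 1e-8)
  }
})

test_that("CI coverage of the focal coefficient is nominal", {
  set.seed(314)
  hits <- 0L
  for (i in 1:500) {
    x <- rnorm(100)
    z <- rnorm(100)
    y <- 1 + 0.5 * x + 0.8 * z + rnorm(100)
    r <- fit_instability_model(y, x, z, stratum = "s")
    row <- r$terms[r$terms$term == "focal", ]
    hits <- hits + (row$ci_low <= 0.5 && 0.5 <= row$ci_high)
  }
  expect_gte(hits / 500, 0.93)
  expect_lte(hits / 500, 0.97)
})

test_that("attenuation arithmetic matches the published-coefficient pattern", {
  mk <- function(beta) structure(list(
    outcome = "fga", stratum = "pan-cancer", model = "m",
    terms = data.frame(term = "focal", beta = beta, se = 0.003,
                       ci_low = 0, ci_high = 1, p_value = 0.01), n = 100),
    class = "RegressionResult")
  # 0.05 unadjusted -> 0.0037 adjusted: 92.6% attenuation
  expect_equal(attenuation(mk(0.05), mk(0.0037)), 0.926)
  expect_equal(attenuation(mk(0.4), mk(0.4)), 0)
  expect_equal(attenuation(mk(0.4), mk(0)), 1)
  a <- attenuation(mk(0), mk(0.1))
  expect_true(is.na(a))
  expect_true(attr(a, "undefined"))
})

test_that("run_model_grid fits the full grid with per-cohort and pooled strata", {
  params <- preset_params("mediation", n_cohorts = 1,
                          n_samples_per_cohort = 120, n_genes = 40,
                          n_planted_coexpressed = 2, g2m_set_size = 20,
                          n_driver_genes = 2, n_passenger_genes = 2,
                          seed = 9)
  co <- simulate_cohort(params, 0)
  roles <- simulated_gene_roles(params)
  grid <- run_model_grid(list(SIM_00 = co), roles$focal, roles$g2m_set)
  # 1 cohort: (2 outcomes x 3 models) per-cohort + the same pan-cancer
  expect_length(grid$results, 12)
  expect_setequal(unique(grid$table$stratum), c("SIM_00", "pan-cancer"))
  expect_setequal(unique(grid$table$model),
                  c("unadjusted", "mki67_adjusted", "g2m_adjusted"))
  expect_equal(nrow(grid$attenuation), 8)  # 2 strata x 2 outcomes x 2 adj
  # G2M score is the better proliferation proxy than MKI67 by construction
  att <- grid$attenuation
  fga_att <- att[att$stratum == "pan-cancer" & att$outcome == "fga", ]
  expect_gt(fga_att$attenuation[fga_att$adjustment == "g2m_adjusted"],
            fga_att$attenuation[fga_att$adjustment == "mki67_adjusted"])
})

test_that("focal_proliferation_correlation behaves on trivial scores", {
  params <- preset_params("mediation", n_cohorts = 2,
                          n_samples_per_cohort = 60, n_genes = 20,
                          n_planted_coexpressed = 2, g2m_set_size = 5,
                          n_driver_genes = 2, n_passenger_genes = 2,
                          seed = 66)
  cohorts <- simulate_multi_cohort(params)
  # score equal to focal log2 expression itself -> rho = 1
  self_score <- unlist(lapply(cohorts, function(co)
    log2(gene_expression(co, "FOCAL") + 1)))
  names(self_score) <- unlist(lapply(cohorts, `[[`, "samples"))
  r <- focal_proliferation_correlation(cohorts, "FOCAL", self_score)
  expect_equal(r$rho, 1)
  # reversed score negates rho
  r2 <- focal_proliferation_correlation(cohorts, "FOCAL", -self_score)
  expect_equal(r2$rho, -1)
  expect_equal(r$n, 120)
})
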