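test_that("mutation_rate counts and missing-gene semantics", {
  co <- make_tiny_cohort()
  expect_equal(mutation_rate(co, co$samples, "TP53"), 0.5)
  expect_true(is.na(mutation_rate(co, co$samples, "ABSENT")))
  expect_error(mutation_rate(co, character(0), "TP53"), "non-empty")
  expect_error(mutation_rate(co, "s99", "TP53"), "outside")

  # 50 random genes vs brute-force counting oracle
  set.seed(6)
  samples <- paste0("s", 1:40)
  genes <- paste0("g", 1:50)
  expr <- matrix(runif(2 * 40, 1, 5), nrow = 2,
                 dimnames = list(c("F", "x"), samples))
  mut <- matrix(rbinom(50 * 40, 1, 0.3), nrow = 50,
                dimnames = list(genes, samples))
  coh <- CohortDataset("R", expr, mut)
  ids <- sample(samples, 17)
  for (g in sample(genes, 50))
    expect_equal(mutation_rate(coh, ids, g), sum(mut[g, ids]) / 17)
})

test_that("delta_enrichment computes deltas with exact sign and unknown status", {
  set.seed(4)
  samples <- paste0("s", 1:16)
  expr <- matrix(c(1:16, runif(16, 1, 5)), nrow = 2, byrow = TRUE,
                 dimnames = list(c("F", "other"), samples))
  # gene A mutated in 2/4 high (s13..s16) and 1/4 low (s1..s4)
  mut <- matrix(0, nrow = 2, ncol = 16,
                dimnames = list(c("A", "B"), samples))
  mut["A", c("s13", "s14", "s1")] <- 1
  mut["B", c("s2", "s15")] <- 1
  coh <- CohortDataset("T1", expr, mut)
  rec <- delta_enrichment(coh, "F", c("A", "B", "missing"))
  a <- rec[rec$gene == "A", ]
  expect_equal(a$rate_high, 0.5)
  expect_equal(a$rate_low, 0.25)
  expect_equal(a$delta, 0.25)
  expect_equal(a$status, "positive")
  b <- rec[rec$gene == "B", ]
  expect_equal(b$delta, 0)
  expect_equal(b$status, "unchanged")
  m <- rec[rec$gene == "missing", ]
  expect_true(is.na(m$delta))
  expect_equal(m$status, "unknown")

  # swapping high/low negates delta and flips positive <-> negative
  g <- quartile_groups(expr["F", ])
  swapped <- g
  swapped$high_ids <- g$low_ids
  swapped$low_ids <- g$high_ids
  rec2 <- delta_enrichment(coh, "F", c("A", "B"), groups = swapped)
  expect_equal(rec2$delta, -rec[rec$gene %in% c("A", "B"), "delta"])
  expect_equal(rec2$status[rec2$gene == "A"], "negative")
  expect_equal(rec2$status[rec2$gene == "B"], "unchanged")
})

test_that("pos_neg_ratio boundary semantics are exact", {
  rec <- function(statuses) data.frame(
    gene = "G", cohort_id = paste0("t", seq_along(statuses)),
    rate_high = 0.5, rate_low = 0.4, delta = 0.1, status = statuses,
    stringsAsFactors = FALSE)
  r <- pos_neg_ratio(rec(c(rep("positive", 6), rep("negative", 2))))
  expect_equal(r$pos_neg_ratio, 3)
  expect_equal(r$classification, "enriched")

  r2 <- pos_neg_ratio(rec(c(rep("positive", 2), rep("negative", 4))))
  expect_equal(r2$pos_neg_ratio, 0.5)
  expect_equal(r2$classification, "depleted")

  # ratio exactly 2 -> neither (strict > 2)
  r3 <- pos_neg_ratio(rec(c(rep("positive", 4), rep("negative", 2))))
  expect_equal(r3$pos_neg_ratio, 2)
  expect_equal(r3$classification, "neither")

  # ratio exactly 0.8 -> depleted (inclusive <= 0.8)
  r4 <- pos_neg_ratio(rec(c(rep("positive", 4), rep("negative", 5))))
  expect_equal(r4$pos_neg_ratio, 0.8)
  expect_equal(r4$classification, "depleted")

  # n_neg = 0 with n_pos > 0 -> +Inf, enriched
  r5 <- pos_neg_ratio(rec(rep("positive", 5)))
  expect_equal(r5$pos_neg_ratio, Inf)
  expect_equal(r5$classification, "enriched")

  # both zero -> undefined ratio, neither
  r6 <- pos_neg_ratio(rec(c("unchanged", "unknown")))
  expect_true(is.na(r6$pos_neg_ratio))
  expect_equal(r6$classification, "neither")
  expect_equal(r6$n_unknown, 1)

  # scale-free: duplicating every tumour type preserves the classification
  for (r_one in list(r, r2, r3, r4, r5)) {
    dup <- pos_neg_ratio(rec(rep(c(rep("positive", r_one$n_pos),
                                   rep("negative", r_one$n_neg)), 2)))
    expect_equal(dup$classification, r_one$classification)
  }
  expect_error(pos_neg_ratio(rec("positive")[0, ]), ">= 1")
})

test_that("encode_status_matrix uses the documented codes and ordering", {
  records <- rbind(
    data.frame(gene = "gA", cohort_id = c("t1", "t2", "t3"),
               rate_high = NA, rate_low = NA, delta = NA,
               status = c("positive", "positive", "negative"),
               stringsAsFactors = FALSE),
    data.frame(gene = "gB", cohort_id = c("t1", "t2"),
               rate_high = NA, rate_low = NA, delta = NA,
               status = c("unchanged", "positive"),
               stringsAsFactors = FALSE))
  m <- encode_status_matrix(records)
  # codes: positive=1 negative=2 unchanged=3 unknown=4 (missing cell)
  expect_equal(unname(m["gA", c("t1", "t2", "t3")]), c(1L, 1L, 2L))
  expect_equal(unname(m["gB", c("t1", "t2", "t3")]), c(3L, 1L, 4L))
  # gA (2 positives) sorts above gB (1 positive)
  expect_identical(rownames(m), c("gA", "gB"))
  # decode inverts the code mapping
  dec <- decode_status_matrix(m)
  expect_equal(unname(dec["gB", ]), c("unchanged", "positive", "unknown"))
})

test_that("drivers classify enriched and non-drivers do not, on simulation", {
  # 53 cohorts mirror a realistic pan-cancer dataset count: under the null the
  # sign-vote gives P(enriched) ~ 1 - pbinom(29, 44, 0.5) ~ 1%, so the 95%
  # specificity bound holds in expectation (it cannot at ~20 cohorts, where
  # the same arithmetic gives ~7%).
  params <- preset_params("mediation", n_cohorts = 53,
                          n_samples_per_cohort = 200, n_genes = 10,
                          n_planted_coexpressed = 2, g2m_set_size = 3,
                          n_driver_genes = 6, n_passenger_genes = 20,
                          driver_enrichment_delta = 0.3, seed = 77)
  cohorts <- simulate_multi_cohort(params)
  roles <- simulated_gene_roles(params)
  all_genes <- c(roles$drivers, roles$passengers)
  deltas <- do.call(rbind, lapply(cohorts, delta_enrichment,
                                  focal_gene = roles$focal,
                                  gene_list = all_genes))
  ratios <- summarise_ratios(deltas)
  drv <- ratios[ratios$gene %in% roles$drivers, ]
  expect_true(all(drv$classification == "enriched"))
  psg <- ratios[ratios$gene %in% roles$passengers, ]
  expect_gte(mean(psg$classification %in% c("neither", "depleted")), 0.95)
})

test_that("alteration_frequency counts layers and recovers planted rates", {
  co <- make_tiny_cohort()
  expect_equal(alteration_frequency(co, "mutation", "TP53"), 0.5)
  expect_error(alteration_frequency(co, "amplification"), "absent")

  params <- preset_params("mediation", n_cohorts = 1,
                          n_samples_per_cohort = 2000, n_genes = 8,
                          n_planted_coexpressed = 1, g2m_set_size = 3,
                          n_driver_genes = 2, n_passenger_genes = 2,
                          amplification_rate = 0.07, seed = 55)
  co2 <- simulate_cohort(params, 0)
  f <- alteration_frequency(co2, "amplification", "FOCAL")
  expect_lt(abs(f - 0.07), 0.015)   # binomial SE oracle at n = 2000
  expect_equal(alteration_frequency(co2, "amplification"), f)
})
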