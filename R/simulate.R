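#' Simulation parameters for the multi-cohort generator
#'
#' The generator draws, per sample, a latent proliferation factor
#' \eqn{P \sim N(0,1)}. The focal gene's log-expression loads on P with
#' `focal_loading`; planted co-expressed genes load (with `planted_loading`)
#' on a second factor C that itself loads `planted_loading` on P, so the
#' latent Pearson correlation between a planted gene and the focal gene is
#' `planted_loading^2 * focal_loading`. At the defaults (0.93^2 * 0.6 = 0.52
#' Pearson, ~0.50 Spearman) planted genes emulate a robustly co-expressed
#' block. Cell-cycle (G2M) signature genes load 0.7 on P and MKI67 loads 0.45
#' (a deliberately weaker proliferation proxy). Expression is the exponential
#' of a per-gene baseline plus the latent log-signal, giving positive,
#' right-skewed, linear-scale values.
#'
#' Driver genes mutate with probability `mutation_base_rate +
#' driver_enrichment_delta` in samples in the top focal-expression quartile
#' and `mutation_base_rate` otherwise; passenger genes always use the base
#' rate. FGA is `plogis` of a linear predictor in P (and optionally the focal
#' z-score directly: `fga_coeff_on_focal = 0` is pure mediation). Mutation
#' count is log-normal with location shifted by P. Survival is exponential
#' with log-hazard `hazard_log_hr_per_sd_focal` per SD of focal
#' log-expression; a `censoring_rate` fraction of subjects is censored
#' uniformly before their event. T stage and histologic grade come from an
#' ordinal-logit latent shifted by `stage_grade_shift` per SD of focal
#' expression.
#'
#' @param n_cohorts,n_samples_per_cohort,n_genes Cohort count, samples per
#'   cohort, and total number of expression genes (focal + planted + G2M set
#'   + MKI67 + null genes).
#' @param n_planted_coexpressed Number of planted co-expressed genes.
#' @param focal_loading,planted_loading Loadings in \[0,1\] (see above).
#' @param g2m_set_size Number of G2M-signature genes (excluding MKI67).
#' @param mutation_base_rate Per-gene Bernoulli mutation rate.
#' @param n_driver_genes,n_passenger_genes Sizes of the mutation universe's
#'   driver and passenger blocks.
#' @param driver_enrichment_delta Additive mutation-rate increase for driver
#'   genes in top-quartile focal samples.
#' @param fga_coeff_on_P,fga_coeff_on_focal Coefficients of the FGA logit.
#' @param mutcount_mean_log Log-scale location of the mutation count.
#' @param hazard_log_hr_per_sd_focal Log hazard ratio per SD of focal
#'   log-expression.
#' @param censoring_rate Fraction of subjects censored, in \[0,1).
#' @param stage_grade_shift Ordinal-logit shift per SD of focal expression.
#' @param amplification_rate Bernoulli rate of the focal gene's synthetic
#'   amplification layer.
#' @param noise_sd Idiosyncratic noise SD multiplier on the log-expression
#'   scale (loadings are calibrated at 1).
#' @param seed Root integer seed; per-cohort substreams are derived from it.
#' @return A `SimulationParams` list.
#' @export
simulation_params <- function(n_cohorts = 10L, n_samples_per_cohort = 300L,
                              n_genes = 532L, n_planted_coexpressed = 50L,
                              focal_loading = 0.6, planted_loading = 0.93,
                              g2m_set_size = 30L,
                              mutation_base_rate = 0.05,
                              n_driver_genes = 20L, n_passenger_genes = 40L,
                              driver_enrichment_delta = 0.25,
                              fga_coeff_on_P = 0.5, fga_coeff_on_focal = 0,
                              mutcount_mean_log = log(50),
                              hazard_log_hr_per_sd_focal = 0.5,
                              censoring_rate = 0.2,
                              stage_grade_shift = 0.8,
                              amplification_rate = 0.03,
                              noise_sd = 1, seed = 1L) {
  p <- list(n_cohorts = as.integer(n_cohorts),
            n_samples_per_cohort = as.integer(n_samples_per_cohort),
            n_genes = as.integer(n_genes),
            n_planted_coexpressed = as.integer(n_planted_coexpressed),
            focal_loading = focal_loading, planted_loading = planted_loading,
            g2m_set_size = as.integer(g2m_set_size),
            mutation_base_rate = mutation_base_rate,
            n_driver_genes = as.integer(n_driver_genes),
            n_passenger_genes = as.integer(n_passenger_genes),
            driver_enrichment_delta = driver_enrichment_delta,
            fga_coeff_on_P = fga_coeff_on_P,
            fga_coeff_on_focal = fga_coeff_on_focal,
            mutcount_mean_log = mutcount_mean_log,
            hazard_log_hr_per_sd_focal = hazard_log_hr_per_sd_focal,
            censoring_rate = censoring_rate,
            stage_grade_shift = stage_grade_shift,
            amplification_rate = amplification_rate,
            noise_sd = noise_sd, seed = as.integer(seed))
  class(p) <- "SimulationParams"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(p$n_cohorts >= 1L, p$n_samples_per_cohort >= 2L, p$n_genes >= 1L)
  if (p$noise_sd <= 0) stop("noise_sd must be positive")
  if (p$focal_loading < 0 || p$focal_loading > 1)
    stop("focal_loading must lie in [0,1]")
  if (p$planted_loading < 0 || p$planted_loading > 1)
    stop("planted_loading must lie in [0,1]")
  if (p$mutation_base_rate <= 0 || p$mutation_base_rate >= 1)
    stop("mutation_base_rate must lie in (0,1)")
  if (p$censoring_rate < 0 || p$censoring_rate >= 1)
    stop("censoring_rate must lie in [0,1)")
  n_structured <- 1L + p$n_planted_coexpressed + p$g2m_set_size + 1L
  if (p$n_planted_coexpressed > p$n_genes - 1L)
    stop("n_planted_coexpressed must be <= n_genes - 1")
  if (n_structured > p$n_genes)
    stop("n_genes too small for planted + G2M + MKI67 + focal genes")
  invisible(p)
}

#' Generator presets
#'
#' `null`: no focal-proliferation coupling, no planted co-expression, no
#' driver enrichment, no survival or stage effect. `mediation`: the focal
#' gene associates with FGA purely through the latent proliferation factor
#' (direct effect 0). `direct-effect`: a residual direct focal effect on FGA
#' (coefficient 0.4) survives proliferation adjustment.
#'
#' @param preset One of `"null"`, `"mediation"`, `"direct-effect"`.
#' @param ... Overrides passed to [simulation_params()].
#' @return A `SimulationParams` list.
#' @export
preset_params <- function(preset = c("mediation", "null", "direct-effect"),
                          ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    "null" = list(focal_loading = 0, planted_loading = 0,
                  driver_enrichment_delta = 0, fga_coeff_on_P = 0.5,
                  fga_coeff_on_focal = 0, hazard_log_hr_per_sd_focal = 0,
                  stage_grade_shift = 0),
    "mediation" = list(focal_loading = 0.6, fga_coeff_on_P = 0.5,
                       fga_coeff_on_focal = 0),
    "direct-effect" = list(focal_loading = 0.6, fga_coeff_on_P = 0.5,
                           fga_coeff_on_focal = 0.4))
  do.call(simulation_params, utils::modifyList(base, list(...)))
}

#' Gene roles implied by a parameter set
#'
#' @param params A `SimulationParams` list.
#' @return List with `focal`, `planted`, `g2m`, `mki67`, `null_genes`,
#'   `drivers`, `passengers` character vectors, plus `g2m_set` (a `GeneSet`
#'   containing the G2M genes and MKI67, as a Hallmark-style set would).
#' @export
simulated_gene_roles <- function(params) {
  n_null <- params$n_genes - 2L - params$n_planted_coexpressed -
    params$g2m_set_size
  roles <- list(
    focal = "FOCAL",
    planted = sprintf("COEX_%03d", seq_len(params$n_planted_coexpressed)),
    g2m = sprintf("G2M_%03d", seq_len(params$g2m_set_size)),
    mki67 = "MKI67",
    null_genes = sprintf("NULL_%03d", seq_len(n_null)),
    drivers = sprintf("DRV_%03d", seq_len(params$n_driver_genes)),
    passengers = sprintf("PSG_%03d", seq_len(params$n_passenger_genes)))
  roles$g2m_set <- structure(
    list(name = "G2M_CHECKPOINT", genes = c(roles$g2m, "MKI67")),
    class = "GeneSet")
  roles
}

cohort_substream_seed <- function(seed, cohort_index) {
  set.seed(seed)
  sample.int(.Machine$integer.max, cohort_index + 1L)[cohort_index + 1L]
}

#' Simulate one cohort
#'
#' Deterministic for a fixed `(params$seed, cohort_index)` pair; each cohort
#' index owns an independent RNG substream so cohorts can be regenerated
#' individually.
#'
#' @param params A `SimulationParams` list.
#' @param cohort_index Zero-based cohort index.
#' @return A validated `CohortDataset` with cohort id `SIM_<index>`.
#' @export
simulate_cohort <- function(params, cohort_index = 0L) {
  validate_params(params)
  roles <- simulated_gene_roles(params)
  n <- params$n_samples_per_cohort
  cohort_id <- sprintf("SIM_%02d", cohort_index)
  samples <- sprintf("%s_S%04d", cohort_id, seq_len(n))

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(cohort_substream_seed(params$seed, cohort_index))

  P <- stats::rnorm(n)
  load_on <- function(factor_vals, loading) {
    loading * factor_vals +
      sqrt(max(0, 1 - loading^2)) * params$noise_sd * stats::rnorm(n)
  }
  focal_z <- load_on(P, params$focal_loading)
  C <- load_on(P, params$planted_loading)

  gene_order <- c(roles$focal, roles$planted, roles$g2m, roles$mki67,
                  roles$null_genes)
  # per-gene baselines fixed within the substream; exp() keeps values positive
  baselines <- stats::runif(length(gene_order), 2, 6)
  names(baselines) <- gene_order
  log_expr <- matrix(NA_real_, nrow = length(gene_order), ncol = n,
                     dimnames = list(gene_order, samples))
  log_expr[roles$focal, ] <- baselines[roles$focal] + focal_z
  for (g in roles$planted)
    log_expr[g, ] <- baselines[g] + load_on(C, params$planted_loading)
  for (g in roles$g2m)
    log_expr[g, ] <- baselines[g] + load_on(P, 0.7)
  log_expr[roles$mki67, ] <- baselines[roles$mki67] + load_on(P, 0.45)
  for (g in roles$null_genes)
    log_expr[g, ] <- baselines[g] + params$noise_sd * stats::rnorm(n)
  expression <- exp(log_expr)

  # mutation layer: drivers enriched in the top focal-expression quartile
  high <- focal_z >= stats::quantile(focal_z, 0.75, type = 7)
  mut_genes <- c(roles$drivers, roles$passengers, roles$focal)
  mutated <- matrix(0, nrow = length(mut_genes), ncol = n,
                    dimnames = list(mut_genes, samples))
  for (g in roles$drivers) {
    rate <- params$mutation_base_rate +
      params$driver_enrichment_delta * high
    mutated[g, ] <- stats::rbinom(n, 1L, pmin(pmax(rate, 0), 1))
  }
  for (g in c(roles$passengers, roles$focal))
    mutated[g, ] <- stats::rbinom(n, 1L, params$mutation_base_rate)

  fga <- stats::plogis(-1.5 + params$fga_coeff_on_P * P +
                         params$fga_coeff_on_focal * focal_z +
                         0.3 * stats::rnorm(n))
  mutation_count <- round(exp(params$mutcount_mean_log + 0.7 * P +
                                0.5 * stats::rnorm(n)))
  metrics <- data.frame(
    sample_id = samples,
    mutation_count = mutation_count,
    fga = fga,
    hrd_score = 10 + 4 * P + 3 * stats::rnorm(n),
    hypoxia_ragnum = 0.5 * P + stats::rnorm(n),
    hypoxia_winter = 0.5 * P + stats::rnorm(n),
    hypoxia_buffa = 0.5 * P + stats::rnorm(n),
    stringsAsFactors = FALSE)

  # ordinal stage / grade via a logistic latent shifted by focal expression
  stage_probs <- c(0.05, 0.25, 0.30, 0.25, 0.15)     # T0..T4
  grade_probs <- c(0.30, 0.40, 0.30)                 # low/mid/high
  draw_ordinal <- function(levels, probs) {
    cuts <- stats::qlogis(cumsum(probs)[-length(probs)])
    latent <- params$stage_grade_shift * focal_z + stats::rlogis(n)
    levels[findInterval(latent, cuts) + 1L]
  }
  os_time <- stats::rexp(n, rate = log(2) / 1000 *
                           exp(params$hazard_log_hr_per_sd_focal * focal_z))
  pfs_time <- stats::rexp(n, rate = log(2) / 700 *
                            exp(params$hazard_log_hr_per_sd_focal * focal_z))
  censor <- function(times) {
    cens <- stats::runif(n) < params$censoring_rate
    obs <- ifelse(cens, times * stats::runif(n), times)
    list(time = obs, event = as.integer(!cens))
  }
  os <- censor(os_time)
  pfs <- censor(pfs_time)
  clinical <- data.frame(
    sample_id = samples,
    t_stage = draw_ordinal(paste0("T", 0:4), stage_probs),
    grade = draw_ordinal(c("low", "mid", "high"), grade_probs),
    os_time = os$time, os_event = os$event,
    pfs_time = pfs$time, pfs_event = pfs$event,
    stringsAsFactors = FALSE)

  alterations <- list(
    amplification = matrix(
      stats::rbinom(n, 1L, params$amplification_rate), nrow = 1L,
      dimnames = list(roles$focal, samples)))

  CohortDataset(cohort_id, expression, mutated, metrics, clinical,
                alterations)
}

#' Simulate a list of mutually independent cohorts
#'
#' @param params A `SimulationParams` list.
#' @return List of `CohortDataset`s named by cohort id (`SIM_00`, ...).
#' @export
simulate_multi_cohort <- function(params) {
  cohorts <- lapply(seq_len(params$n_cohorts) - 1L,
                    function(i) simulate_cohort(params, i))
  names(cohorts) <- vapply(cohorts, function(co) co$cohort_id, "")
  cohorts
}

#' Write simulated cohorts as a directory tree of TSV files
#'
#' Produces per-cohort `expression.tsv`, `mutations.tsv`, `metrics.tsv` and
#' `clinical.tsv`, plus the GMT gene set, the driver list used, and a
#' `config.dcf` consumable by [read_config()].
#'
#' @param params A `SimulationParams` list.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_simulated_cohorts <- function(params, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  roles <- simulated_gene_roles(params)
  cohorts <- simulate_multi_cohort(params)
  blocks <- list(c(focal_gene = roles$focal,
                   gene_set_gmt = "g2m.gmt",
                   gene_set_name = roles$g2m_set$name,
                   driver_list = "drivers.txt"))
  for (co in cohorts) {
    sub <- file.path(out_dir, co$cohort_id)
    dir.create(sub, showWarnings = FALSE)
    write_matrix(co$expression, file.path(sub, "expression.tsv"))
    idx <- which(co$mutated == 1, arr.ind = TRUE)
    mut_long <- data.frame(
      sample_id = colnames(co$mutated)[idx[, 2]],
      gene = rownames(co$mutated)[idx[, 1]],
      variant_class = "missense", stringsAsFactors = FALSE)
    mut_long <- mut_long[order(mut_long$sample_id, mut_long$gene), ]
    write_result_table(mut_long, file.path(sub, "mutations.tsv"))
    write_result_table(co$metrics, file.path(sub, "metrics.tsv"))
    write_result_table(co$clinical, file.path(sub, "clinical.tsv"))
    blocks <- c(blocks, list(c(
      cohort_id = co$cohort_id,
      expression = file.path(co$cohort_id, "expression.tsv"),
      mutations = file.path(co$cohort_id, "mutations.tsv"),
      metrics = file.path(co$cohort_id, "metrics.tsv"),
      clinical = file.path(co$cohort_id, "clinical.tsv"))))
  }
  writeLines(paste0(roles$g2m_set$name, "\tsimulated G2M checkpoint set\t",
                    paste(roles$g2m_set$genes, collapse = "\t")),
             file.path(out_dir, "g2m.gmt"))
  writeLines(roles$drivers, file.path(out_dir, "drivers.txt"))
  dcf <- do.call(rbind, lapply(blocks, function(b)
    paste0(names(b), ": ", b, collapse = "\n")))
  writeLines(paste(dcf, collapse = "\n\n"), file.path(out_dir, "config.dcf"))
  invisible(out_dir)
}
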