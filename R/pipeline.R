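#' Run the full stratification pipeline and write result tables
#'
#' Executes, over a list of cohorts: (1) per-cohort expression-range and
#' quartile stratification on the focal gene; (2) per-cohort focal
#' co-expression plus the cross-cohort consistency vote and ordered matrix;
#' (3) per-cohort driver-mutation delta enrichment with the cross-cohort
#' pos/neg-ratio summary and encoded status matrix; (4) pooled high/low
#' comparisons of molecular metrics; (5) the proliferation-adjusted
#' regression grid with attenuation summaries; (6) pooled stage/grade
#' contingency tests and Kaplan-Meier / log-rank survival comparisons.
#' Every result is written as TSV into `out_dir` with fixed column order, so
#' repeated runs on the same inputs are byte-identical.
#'
#' Mutation enrichment stratifies within each cohort (tumour type); metric,
#' stage/grade and survival comparisons stratify on the pooled focal
#' expression values.
#'
#' @param cohorts List of `CohortDataset`s.
#' @param focal_gene Focal gene identifier.
#' @param gene_set `GeneSet` for the proliferation score.
#' @param driver_genes Character vector of driver gene identifiers.
#' @param out_dir Output directory (created if needed).
#' @param min_frac,rho_thresh,sig_thresh,sig_field Consistency-vote settings.
#' @param pseudocount log2 pseudocount for expression transforms.
#' @return Invisibly, a list with the in-memory results (`consistency`,
#'   `ratio_summary`, `model_grid`, `metric_comparisons`, `stage_grade`,
#'   `survival`).
#' @export
run_pipeline <- function(cohorts, focal_gene, gene_set, driver_genes,
                         out_dir, min_frac = 0.8, rho_thresh = 0.3,
                         sig_thresh = 0.05, sig_field = "q",
                         pseudocount = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(names(cohorts)))
    names(cohorts) <- vapply(cohorts, `[[`, "", "cohort_id")

  # 1. expression range + per-cohort stratification
  ranges <- data.frame(
    cohort_id = names(cohorts),
    expression_range = vapply(cohorts, function(co)
      expression_range(gene_expression(co, focal_gene)), 0),
    stringsAsFactors = FALSE)
  write_result_table(ranges, file.path(out_dir, "expression_range.tsv"))

  groups_by_cohort <- lapply(cohorts, function(co)
    quartile_groups(gene_expression(co, focal_gene)))
  strat_rows <- do.call(rbind, lapply(names(cohorts), function(nm) {
    g <- groups_by_cohort[[nm]]
    ids <- names(g$focal_values)
    grp <- ifelse(ids %in% g$high_ids, "high",
                  ifelse(ids %in% g$low_ids, "low", "mid"))
    data.frame(cohort_id = nm, sample_id = ids,
               focal_value = unname(g$focal_values), group = grp,
               stringsAsFactors = FALSE)
  }))
  write_result_table(strat_rows, file.path(out_dir, "stratification.tsv"))

  # 2. co-expression consistency
  records <- lapply(cohorts, correlate_focal, focal_gene = focal_gene)
  write_result_table(do.call(rbind, records),
                     file.path(out_dir, "correlations.tsv"))
  consistency <- consistency_vote(records, min_frac = min_frac,
                                  rho_thresh = rho_thresh,
                                  sig_thresh = sig_thresh,
                                  sig_field = sig_field)
  write_result_table(consistency, file.path(out_dir, "consistency.tsv"))
  ordered <- suppressWarnings(build_ordered_matrix(consistency, records))
  om <- data.frame(gene = rownames(ordered$matrix),
                   group = as.integer(ordered$group), ordered$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_result_table(om, file.path(out_dir, "ordered_matrix.tsv"))

  # 3. mutation enrichment (within-cohort stratification)
  deltas <- do.call(rbind, lapply(names(cohorts), function(nm)
    delta_enrichment(cohorts[[nm]], focal_gene, driver_genes,
                     groups = groups_by_cohort[[nm]])))
  write_result_table(deltas, file.path(out_dir, "delta_records.tsv"))
  ratios <- summarise_ratios(deltas)
  write_result_table(ratios, file.path(out_dir, "ratio_summary.tsv"))
  status <- encode_status_matrix(deltas)
  write_matrix(status, file.path(out_dir, "status_matrix.tsv"))

  # 4. pooled metric comparisons
  pooled_focal <- unlist(lapply(cohorts, function(co) {
    v <- gene_expression(co, focal_gene)
    stats::setNames(as.numeric(v), names(v))
  }), use.names = FALSE)
  names(pooled_focal) <- unlist(lapply(cohorts, `[[`, "samples"))
  pooled_groups <- quartile_groups(pooled_focal)
  metric_rows <- do.call(rbind, lapply(names(cohorts), function(nm) {
    cmp <- compare_metrics(cohorts[[nm]], pooled_groups)
    if (is.null(cmp)) return(NULL)
    cbind(data.frame(cohort_id = nm, stringsAsFactors = FALSE), cmp)
  }))
  if (!is.null(metric_rows))
    write_result_table(metric_rows,
                       file.path(out_dir, "metric_comparisons.tsv"))

  # 5. proliferation-adjusted regression grid
  grid <- run_model_grid(cohorts, focal_gene, gene_set,
                         pseudocount = pseudocount)
  write_result_table(grid$table, file.path(out_dir, "regression_results.tsv"))
  write_result_table(grid$attenuation, file.path(out_dir, "attenuation.tsv"))

  # 6. clinical / survival
  sg <- stage_grade_tables(cohorts, pooled_groups)
  sg_rows <- do.call(rbind, lapply(names(sg), function(v) {
    tst <- sg[[v]]$test
    data.frame(variable = v,
               statistic = if (is.null(tst)) NA_real_ else tst$statistic,
               df = if (is.null(tst)) NA_real_ else tst$df,
               p_value = if (is.null(tst)) NA_real_ else tst$p_value,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(sg_rows))
    write_result_table(sg_rows, file.path(out_dir, "stage_grade_tests.tsv"))
  pct_rows <- do.call(rbind, lapply(names(sg), function(v) {
    p <- sg[[v]]$percentages
    grid <- expand.grid(group = rownames(p), category = colnames(p),
                        stringsAsFactors = FALSE)
    data.frame(variable = v, group = grid$group, category = grid$category,
               percentage = p[cbind(grid$group, grid$category)],
               count = sg[[v]]$table[cbind(grid$group, grid$category)],
               stringsAsFactors = FALSE)
  }))
  if (!is.null(pct_rows))
    write_result_table(pct_rows,
                       file.path(out_dir, "stage_grade_distributions.tsv"))

  surv_rows <- list(); km_rows <- list()
  for (ep in c("pfs", "os")) {
    has_ep <- any(vapply(cohorts, function(co)
      !is.null(co$clinical) && paste0(ep, "_time") %in% names(co$clinical),
      TRUE))
    if (!has_ep) next
    sc <- survival_comparison(cohorts, pooled_groups, endpoint = ep)
    surv_rows[[ep]] <- data.frame(
      endpoint = ep, chi_square = sc$test$chi_square,
      p_value = sc$test$p_value, n_high = sc$test$n_high,
      n_low = sc$test$n_low, events_high = sc$test$events_high,
      events_low = sc$test$events_low, stringsAsFactors = FALSE)
    for (grp in c("high", "low")) {
      cv <- if (grp == "high") sc$curve_high else sc$curve_low
      km_rows[[paste(ep, grp)]] <- data.frame(
        endpoint = ep, group = grp, time = cv$event_times,
        survival = cv$survival_prob, n_at_risk = cv$n_at_risk,
        n_events = cv$n_events, stringsAsFactors = FALSE)
    }
  }
  if (length(surv_rows) > 0L) {
    write_result_table(do.call(rbind, surv_rows),
                       file.path(out_dir, "survival_tests.tsv"))
    write_result_table(do.call(rbind, km_rows),
                       file.path(out_dir, "km_curves.tsv"))
  }

  invisible(list(consistency = consistency, ratio_summary = ratios,
                 model_grid = grid, metric_comparisons = metric_rows,
                 stage_grade = sg,
                 survival = if (length(surv_rows)) do.call(rbind, surv_rows)))
}

#' Load the cohorts described by a configuration file
#'
#' @param config A list from [read_config()].
#' @return List with `cohorts`, `focal_gene`, and (when configured)
#'   `gene_set` and `driver_genes`.
#' @export
load_configured_cohorts <- function(config) {
  cohorts <- lapply(config$cohorts, function(cc) {
    expr <- read_expression_table(cc$expression)
    mutated <- if (!is.null(cc$mutations) && !is.na(cc$mutations))
      read_mutation_table(cc$mutations, samples = colnames(expr))
    metrics <- if (!is.null(cc$metrics) && !is.na(cc$metrics))
      read_sample_table(cc$metrics)
    clinical <- if (!is.null(cc$clinical) && !is.na(cc$clinical))
      read_sample_table(cc$clinical)
    assemble_cohort(expr, mutated, metrics, clinical,
                    cohort_id = cc$cohort_id)
  })
  names(cohorts) <- vapply(config$cohorts, `[[`, "", "cohort_id")
  list(cohorts = cohorts, focal_gene = config$focal_gene,
       gene_set = if (!is.null(config$gene_set_gmt) &&
                      !is.na(config$gene_set_gmt))
         read_gene_set_gmt(config$gene_set_gmt, config$gene_set_name),
       driver_genes = if (!is.null(config$driver_list) &&
                          !is.na(config$driver_list))
         read_driver_list(config$driver_list))
}

#' Command-line entry point
#'
#' Two subcommands. `simulate --preset P --seed S --out DIR` writes a
#' simulated multi-cohort directory tree (TSVs, GMT, driver list, config).
#' `run --config FILE --out DIR` loads the configured cohorts and executes
#' [run_pipeline()].
#'
#' @param args Character vector of arguments (defaults to the command line).
#' @return Exit status, invisibly.
#' @export
pancanstrat_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: pancanstrat simulate --out DIR [--preset null|mediation|direct-effect]",
    "                            [--seed INT] [--n-cohorts INT] [--n-samples INT]",
    "       pancanstrat run --config FILE --out DIR [--focal-gene GENE]",
    sep = "\n")
  if (length(args) < 1L) { message(usage); return(invisible(1L)) }
  cmd <- args[[1L]]
  opts <- list()
  rest <- args[-1L]
  i <- 1L
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[[i]])
    opts[[key]] <- rest[[i + 1L]]
    i <- i + 2L
  }
  if (cmd == "simulate") {
    if (is.null(opts$out)) { message(usage); return(invisible(1L)) }
    params <- preset_params(
      if (is.null(opts$preset)) "mediation" else opts$preset,
      seed = if (is.null(opts$seed)) 1L else as.integer(opts$seed),
      n_cohorts = if (is.null(opts[["n-cohorts"]])) 3L else
        as.integer(opts[["n-cohorts"]]),
      n_samples_per_cohort = if (is.null(opts[["n-samples"]])) 150L else
        as.integer(opts[["n-samples"]]))
    write_simulated_cohorts(params, opts$out)
    message("wrote simulated cohorts to ", opts$out)
    return(invisible(0L))
  }
  if (cmd == "run") {
    if (is.null(opts$config) || is.null(opts$out)) {
      message(usage); return(invisible(1L))
    }
    config <- read_config(opts$config)
    loaded <- load_configured_cohorts(config)
    focal <- if (!is.null(opts[["focal-gene"]])) opts[["focal-gene"]] else
      loaded$focal_gene
    run_pipeline(loaded$cohorts, focal, loaded$gene_set,
                 loaded$driver_genes, opts$out)
    message("wrote pipeline results to ", opts$out)
    return(invisible(0L))
  }
  message(usage)
  invisible(1L)
}
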