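#' G2M proliferation score
#'
#' Per-sample mean of per-gene z-scores of log2-transformed expression over
#' the gene set, with MKI67 excluded by default (it is used separately as a
#' single-gene proliferation proxy). z-scores use the sample standard
#' deviation (n-1 denominator); zero-variance genes are dropped with a
#' warning.
#'
#' @param cohort A `CohortDataset`.
#' @param gene_set A `GeneSet` (see [read_gene_set_gmt()]).
#' @param exclude Genes to remove from the set before scoring.
#' @param pseudocount Added before log2.
#' @return A `ProliferationScore` list: `score` (named per-sample vector),
#'   `gene_set_name`, `n_genes_used`, `excluded_genes` (requested exclusions
#'   plus genes dropped as absent or zero-variance).
#' @export
g2m_score <- function(cohort, gene_set, exclude = "MKI67", pseudocount = 1) {
  wanted <- setdiff(gene_set$genes, exclude)
  present <- intersect(wanted, rownames(cohort$expression))
  if (length(present) == 0L)
    stop("no usable genes in the gene set after exclusions")
  logx <- log2(cohort$expression[present, , drop = FALSE] + pseudocount)
  sds <- apply(logx, 1L, stats::sd)
  flat <- is.na(sds) | sds == 0
  if (any(flat)) {
    warning(sprintf("dropping %d zero-variance gene(s) from the score",
                    sum(flat)), call. = FALSE)
    logx <- logx[!flat, , drop = FALSE]
    sds <- sds[!flat]
  }
  if (nrow(logx) == 0L) stop("no usable genes in the gene set after exclusions")
  z <- (logx - rowMeans(logx)) / sds
  structure(list(score = colMeans(z),
                 gene_set_name = gene_set$name,
                 n_genes_used = nrow(logx),
                 excluded_genes = union(exclude,
                                        setdiff(wanted,
                                                rownames(logx)))),
            class = "ProliferationScore")
}

#' Per-sample covariate table for the instability models
#'
#' log2 (with pseudocount) for expression, natural log1p for mutation count,
#' FGA passed through.
#'
#' @param cohort A `CohortDataset` with a metrics table.
#' @param focal_gene Focal gene identifier.
#' @param pseudocount Added to expression before log2.
#' @return data.frame with `sample_id`, `focal_log2`, `mki67_log2` (NA if
#'   MKI67 absent), `log1p_mutation_count`, `fga`.
#' @export
transform_covariates <- function(cohort, focal_gene, pseudocount = 1) {
  expr <- cohort$expression
  if (any(expr < 0, na.rm = TRUE)) stop("negative expression values")
  focal <- gene_expression(cohort, focal_gene)
  mki67 <- if ("MKI67" %in% rownames(expr)) expr["MKI67", ] else
    rep(NA_real_, ncol(expr))
  mt <- cohort$metrics
  data.frame(
    sample_id = colnames(expr),
    focal_log2 = log2(focal + pseudocount),
    mki67_log2 = log2(mki67 + pseudocount),
    log1p_mutation_count = if (!is.null(mt$mutation_count))
      log1p(mt$mutation_count[match(colnames(expr), mt$sample_id)]) else
        NA_real_,
    fga = if (!is.null(mt$fga)) mt$fga[match(colnames(expr), mt$sample_id)]
      else NA_real_,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Ordinary least squares fit of an instability outcome on focal expression
#'
#' Intercept always included; optional single proliferation covariate.
#' Returns per-term beta, SE, two-sided t-test p and 95% CI
#' (`beta +/- t(0.975, n-k) * se`).
#'
#' @param outcome,focal Numeric per-sample vectors.
#' @param covariate Optional numeric covariate vector (same length).
#' @param stratum Label recorded in the result (cohort id or "pan-cancer").
#' @param outcome_name,model Labels recorded in the result.
#' @return A `RegressionResult` list: `outcome`, `stratum`, `model`, `terms`
#'   (data.frame term/beta/se/ci_low/ci_high/p_value), `n`, `residuals`,
#'   `fitted`.
#' @export
fit_instability_model <- function(outcome, focal, covariate = NULL,
                                  stratum = "pan-cancer",
                                  outcome_name = "outcome",
                                  model = if (is.null(covariate))
                                    "unadjusted" else "adjusted") {
  df <- data.frame(y = outcome, focal = focal)
  if (!is.null(covariate)) df$covariate <- covariate
  df <- df[stats::complete.cases(df), , drop = FALSE]
  k <- ncol(df)                      # predictors + intercept
  if (nrow(df) < k + 2L)
    stop("insufficient complete cases for the model")
  fit <- stats::lm(y ~ ., data = df)
  if (anyNA(stats::coef(fit)))
    stop("singular design: predictors are perfectly collinear")
  sm <- summary(fit)$coefficients
  tcrit <- stats::qt(0.975, fit$df.residual)
  terms <- data.frame(term = rownames(sm), beta = sm[, 1], se = sm[, 2],
                      ci_low = sm[, 1] - tcrit * sm[, 2],
                      ci_high = sm[, 1] + tcrit * sm[, 2],
                      p_value = sm[, 4], row.names = NULL,
                      stringsAsFactors = FALSE)
  terms$term[terms$term == "(Intercept)"] <- "intercept"
  structure(list(outcome = outcome_name, stratum = stratum, model = model,
                 terms = terms, n = nrow(df),
                 residuals = stats::residuals(fit),
                 fitted = stats::fitted(fit)),
            class = "RegressionResult")
}

#' @export
print.RegressionResult <- function(x, ...) {
  cat(sprintf("RegressionResult [%s | %s | %s], n = %d\n",
              x$outcome, x$stratum, x$model, x$n))
  print(x$terms, digits = 4)
  invisible(x)
}

focal_beta <- function(result) {
  result$terms$beta[result$terms$term == "focal"]
}

#' Proportional attenuation of the focal coefficient after adjustment
#'
#' `1 - beta_adjusted / beta_unadjusted` for the focal term; positive values
#' mean the adjusted coefficient moved toward zero. Returns `NA` with
#' attribute `undefined = TRUE` when the unadjusted coefficient is zero.
#'
#' @param unadjusted,adjusted `RegressionResult`s for the same outcome and
#'   stratum.
#' @return Single numeric attenuation value.
#' @export
attenuation <- function(unadjusted, adjusted) {
  if (!identical(unadjusted$outcome, adjusted$outcome) ||
      !identical(unadjusted$stratum, adjusted$stratum))
    stop("results must share outcome and stratum")
  b0 <- focal_beta(unadjusted)
  b1 <- focal_beta(adjusted)
  if (length(b0) != 1L || length(b1) != 1L)
    stop("focal term missing from a result")
  if (b0 == 0) return(structure(NA_real_, undefined = TRUE))
  1 - b1 / b0
}

#' Fit the full model grid: outcomes x adjustment models x strata
#'
#' For each outcome (`fga`, `log1p_mutation_count`) and each model
#' (`unadjusted`, `mki67_adjusted`, `g2m_adjusted`), fits one OLS per cohort
#' and one on the pooled pan-cancer table. G2M scores and covariate
#' transforms are computed within each cohort before pooling (set
#' `pool_raw = TRUE` to z-score and transform on the concatenated table
#' instead, the single-table pan-cancer reading). Per-stratum failures are
#' recorded as warnings and skipped.
#'
#' @param cohorts List of `CohortDataset`s.
#' @param focal_gene Focal gene identifier.
#' @param gene_set `GeneSet` for the proliferation score.
#' @param pseudocount Passed to the transforms.
#' @param pool_raw Pool raw tables before standardisation.
#' @return List with `results` (list of `RegressionResult`s), `table`
#'   (forest-plot-ready data.frame of focal-term rows with a `significant`
#'   flag at p < 0.05), and `attenuation` (data.frame per stratum x outcome
#'   x adjustment).
#' @export
run_model_grid <- function(cohorts, focal_gene, gene_set, pseudocount = 1,
                           pool_raw = FALSE) {
  if (length(cohorts) < 1L) stop("need >= 1 cohort")
  per_cohort <- lapply(cohorts, function(co) {
    cov <- transform_covariates(co, focal_gene, pseudocount)
    cov$g2m_score <- g2m_score(co, gene_set,
                               pseudocount = pseudocount)$score
    cov$stratum <- co$cohort_id
    cov
  })
  pooled <- do.call(rbind, per_cohort)
  if (pool_raw) {
    # recompute score and transforms on the concatenated table
    all_expr <- do.call(cbind, lapply(cohorts, `[[`, "expression"))
    shared <- Reduce(intersect, lapply(cohorts,
                                       function(co) rownames(co$expression)))
    pseudo <- CohortDataset("pan-cancer",
                            all_expr[shared, , drop = FALSE],
                            metrics = do.call(rbind, lapply(cohorts,
                                                            `[[`, "metrics")))
    cov <- transform_covariates(pseudo, focal_gene, pseudocount)
    cov$g2m_score <- g2m_score(pseudo, gene_set,
                               pseudocount = pseudocount)$score
    cov$stratum <- "pan-cancer"
    pooled <- cov
  } else {
    pooled$stratum <- "pan-cancer"
  }
  strata <- c(per_cohort, list(pooled))

  outcomes <- c("fga", "log1p_mutation_count")
  models <- list(unadjusted = NULL, mki67_adjusted = "mki67_log2",
                 g2m_adjusted = "g2m_score")
  results <- list()
  for (tab in strata) {
    stratum <- tab$stratum[1L]
    for (oc in outcomes) {
      if (all(is.na(tab[[oc]]))) next
      for (mn in names(models)) {
        cov_col <- models[[mn]]
        res <- tryCatch(
          fit_instability_model(tab[[oc]], tab$focal_log2,
                                if (!is.null(cov_col)) tab[[cov_col]],
                                stratum = stratum, outcome_name = oc,
                                model = mn),
          error = function(e) {
            warning(sprintf("skipping %s | %s | %s: %s", stratum, oc, mn,
                            conditionMessage(e)), call. = FALSE)
            NULL
          })
        if (!is.null(res)) results[[length(results) + 1L]] <- res
      }
    }
  }

  table <- do.call(rbind, lapply(results, function(r) {
    row <- r$terms[r$terms$term == "focal", , drop = FALSE]
    data.frame(stratum = r$stratum, outcome = r$outcome, model = r$model,
               beta = row$beta, se = row$se, ci_low = row$ci_low,
               ci_high = row$ci_high, p_value = row$p_value, n = r$n,
               significant = row$p_value < 0.05, stringsAsFactors = FALSE)
  }))

  att_rows <- list()
  for (st in unique(table$stratum)) for (oc in outcomes) {
    pick <- function(mn) Filter(function(r)
      r$stratum == st && r$outcome == oc && r$model == mn, results)
    un <- pick("unadjusted")
    if (length(un) != 1L) next
    for (mn in c("mki67_adjusted", "g2m_adjusted")) {
      adj <- pick(mn)
      if (length(adj) != 1L) next
      att_rows[[length(att_rows) + 1L]] <- data.frame(
        stratum = st, outcome = oc, adjustment = mn,
        beta_unadjusted = focal_beta(un[[1L]]),
        beta_adjusted = focal_beta(adj[[1L]]),
        attenuation = as.numeric(attenuation(un[[1L]], adj[[1L]])),
        stringsAsFactors = FALSE)
    }
  }
  list(results = results, table = table,
       attenuation = do.call(rbind, att_rows))
}

#' Pooled Spearman correlation between focal expression and a score
#'
#' @param cohorts List of `CohortDataset`s.
#' @param focal_gene Focal gene identifier.
#' @param scores Named list (by cohort id) of per-sample score vectors, or a
#'   single named vector covering all pooled samples.
#' @return List with `rho`, `p_value`, `n`.
#' @export
focal_proliferation_correlation <- function(cohorts, focal_gene, scores) {
  focal <- unlist(lapply(cohorts, function(co)
    log2(gene_expression(co, focal_gene) + 1)))
  names(focal) <- unlist(lapply(cohorts, `[[`, "samples"))
  score <- if (is.list(scores)) unlist(unname(scores)) else scores
  shared <- intersect(names(focal), names(score))
  if (length(shared) < 10L) stop("need >= 10 pooled samples")
  x <- focal[shared]; y <- score[shared]
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  rho <- stats::cor(rank(x[ok]), rank(y[ok]))
  p <- if (abs(rho) >= 1) 0 else
    2 * stats::pt(-abs(rho * sqrt((n - 2) / (1 - rho^2))), n - 2)
  list(rho = rho, p_value = p, n = n)
}
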