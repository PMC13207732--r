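#' Spearman correlation of every gene against the focal gene
#'
#' Mid-rank Spearman rho with tie correction (Pearson correlation of
#' mid-ranks), two-sided p by the t approximation (exact AS89 method via
#' [stats::cor.test()] for untied samples with n < 10), and Benjamini-
#' Hochberg q-values computed across all genes within the cohort. Missing
#' cells are handled pairwise: each gene's statistic uses the samples where
#' both that gene and the focal gene are observed; genes with fewer than 3
#' complete pairs are omitted with a warning.
#'
#' @param cohort A `CohortDataset`.
#' @param focal_gene Focal gene identifier (must be in the cohort).
#' @return data.frame of `CorrelationRecord`s: `gene`, `cohort_id`, `rho`,
#'   `p_value`, `q_value`, `n_pairs`.
#' @export
correlate_focal <- function(cohort, focal_gene) {
  expr <- cohort$expression
  if (!focal_gene %in% rownames(expr))
    stop(sprintf("focal gene '%s' not found in cohort '%s'",
                 focal_gene, cohort$cohort_id))
  focal <- expr[focal_gene, ]
  others <- setdiff(rownames(expr), focal_gene)
  n_all <- ncol(expr)

  stat_one <- function(g) {
    x <- expr[g, ]
    ok <- !is.na(x) & !is.na(focal)
    n <- sum(ok)
    if (n < 3L) return(c(NA_real_, NA_real_, n))
    x <- x[ok]; y <- focal[ok]
    if (n < 10L && !anyDuplicated(x) && !anyDuplicated(y)) {
      ct <- stats::cor.test(x, y, method = "spearman", exact = TRUE)
      return(c(unname(ct$estimate), ct$p.value, n))
    }
    rho <- stats::cor(rank(x), rank(y))
    if (is.na(rho)) return(c(NA_real_, NA_real_, n))   # zero-variance gene
    p <- if (abs(rho) >= 1) 0 else
      2 * stats::pt(-abs(rho * sqrt((n - 2) / (1 - rho^2))), n - 2)
    c(rho, p, n)
  }

  complete <- !anyNA(expr)
  if (complete && n_all >= 10L) {
    # fast path: rank once, correlate all genes against the focal ranks
    rk <- t(apply(expr[others, , drop = FALSE], 1L, rank))
    fr <- rank(focal)
    rho <- as.vector(stats::cor(t(rk), fr))
    tstat <- rho * sqrt((n_all - 2) / pmax(1 - rho^2, .Machine$double.eps))
    p <- ifelse(abs(rho) >= 1, 0, 2 * stats::pt(-abs(tstat), n_all - 2))
    out <- data.frame(gene = others, cohort_id = cohort$cohort_id,
                      rho = rho, p_value = p, n_pairs = n_all,
                      stringsAsFactors = FALSE)
    out <- out[!is.na(out$rho), , drop = FALSE]
  } else {
    stats3 <- t(vapply(others, stat_one, numeric(3)))
    out <- data.frame(gene = others, cohort_id = cohort$cohort_id,
                      rho = stats3[, 1], p_value = stats3[, 2],
                      n_pairs = as.integer(stats3[, 3]),
                      stringsAsFactors = FALSE)
    dropped <- is.na(out$rho)
    if (any(dropped))
      warning(sprintf("omitting %d gene(s) with < 3 complete pairs or zero variance",
                      sum(dropped)), call. = FALSE)
    out <- out[!dropped, , drop = FALSE]
  }
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out[, c("gene", "cohort_id", "rho", "p_value", "q_value", "n_pairs")]
}

#' Classify a correlation record as positive / negative / neither
#'
#' Positive iff `rho >= rho_thresh` and the chosen significance field is
#' `<= sig_thresh`; negative symmetrically; boundaries inclusive.
#'
#' @param rho,sig Correlation coefficient and its significance value (q or p
#'   depending on `sig_field` at the call site).
#' @param rho_thresh,sig_thresh Classification thresholds.
#' @return `"positive"`, `"negative"` or `"neither"` (vectorised).
#' @export
classify_direction <- function(rho, sig, rho_thresh = 0.3, sig_thresh = 0.05) {
  ifelse(sig <= sig_thresh & rho >= rho_thresh, "positive",
         ifelse(sig <= sig_thresh & rho <= -rho_thresh, "negative", "neither"))
}

#' Cross-cohort consistency vote
#'
#' Only genes present in every cohort's record set are considered. A gene is
#' `consistent_positive` when it classifies positive in at least
#' `floor(min_frac * n_datasets)` cohorts (e.g. 42 of 53 at the default
#' 0.8), and symmetrically for `consistent_negative`. `mean_rho` averages
#' over all cohorts, significant or not.
#'
#' @param records_by_cohort Named list of [correlate_focal()] data.frames.
#' @param min_frac Required fraction of datasets.
#' @param rho_thresh,sig_thresh,sig_field Classification thresholds; the
#'   significance field is `"q"` (default, FDR-controlled) or `"p"`.
#' @return data.frame of `ConsistencyResult`s: `gene`, `n_datasets`,
#'   `n_pos_sig`, `n_neg_sig`, `mean_rho`, `label`.
#' @export
consistency_vote <- function(records_by_cohort, min_frac = 0.8,
                             rho_thresh = 0.3, sig_thresh = 0.05,
                             sig_field = c("q", "p")) {
  sig_field <- match.arg(sig_field)
  if (length(records_by_cohort) < 2L) stop("need >= 2 cohorts")
  shared <- Reduce(intersect, lapply(records_by_cohort, `[[`, "gene"))
  if (length(shared) == 0L)
    stop("no genes shared across all cohorts")
  n_datasets <- length(records_by_cohort)
  threshold <- floor(min_frac * n_datasets)
  sig_col <- if (sig_field == "q") "q_value" else "p_value"

  rho_mat <- vapply(records_by_cohort, function(rec)
    rec$rho[match(shared, rec$gene)], numeric(length(shared)))
  cls_mat <- vapply(records_by_cohort, function(rec) {
    i <- match(shared, rec$gene)
    classify_direction(rec$rho[i], rec[[sig_col]][i], rho_thresh, sig_thresh)
  }, character(length(shared)))
  if (length(shared) == 1L) {
    rho_mat <- matrix(rho_mat, nrow = 1L)
    cls_mat <- matrix(cls_mat, nrow = 1L)
  }
  n_pos <- rowSums(cls_mat == "positive")
  n_neg <- rowSums(cls_mat == "negative")
  label <- ifelse(n_pos >= threshold, "consistent_positive",
                  ifelse(n_neg >= threshold, "consistent_negative", "none"))
  data.frame(gene = shared, n_datasets = n_datasets,
             n_pos_sig = n_pos, n_neg_sig = n_neg,
             mean_rho = rowMeans(rho_mat), label = label,
             stringsAsFactors = FALSE)
}

#' Heatmap-ready ordered correlation matrix for consistent genes
#'
#' Rows are restricted to consistently labelled genes and split into group 1
#' (raw rho > 0 in every cohort) and group 2 (rho < 0 in at least one
#' cohort); within each group rows are ordered by descending mean rho. Cells
#' hold raw correlations including non-significant ones.
#'
#' @param results A [consistency_vote()] data.frame.
#' @param records_by_cohort The per-cohort records the vote was computed on.
#' @return List with `matrix` (gene x cohort) and `group` (named vector of
#'   1/2 per retained gene); both empty, with a warning, if no gene is
#'   consistent.
#' @export
build_ordered_matrix <- function(results, records_by_cohort) {
  keep <- results[results$label != "none", , drop = FALSE]
  if (nrow(keep) == 0L) {
    warning("no consistently labelled genes", call. = FALSE)
    return(list(matrix = matrix(numeric(0), nrow = 0,
                                ncol = length(records_by_cohort),
                                dimnames = list(NULL,
                                                names(records_by_cohort))),
                group = integer(0)))
  }
  rho_mat <- vapply(records_by_cohort, function(rec)
    rec$rho[match(keep$gene, rec$gene)], numeric(nrow(keep)))
  if (nrow(keep) == 1L) rho_mat <- matrix(rho_mat, nrow = 1L)
  dimnames(rho_mat) <- list(keep$gene, names(records_by_cohort))
  group <- ifelse(apply(rho_mat > 0, 1L, all), 1L, 2L)
  ord <- order(group, -keep$mean_rho)
  list(matrix = rho_mat[ord, , drop = FALSE],
       group = stats::setNames(group[ord], keep$gene[ord]))
}

#' Count recurrence of externally produced labels across cohorts
#'
#' Generic integration step for pathway labels produced outside this
#' package: for each label, the number of cohorts whose set contains it.
#'
#' @param label_sets Named list (one element per cohort) of character
#'   vectors.
#' @return Named integer vector sorted by descending count (ties broken
#'   alphabetically).
#' @export
recurrence_count <- function(label_sets) {
  if (length(label_sets) < 1L) stop("need >= 1 cohort")
  all_labels <- unlist(lapply(label_sets, unique), use.names = FALSE)
  if (length(all_labels) == 0L) return(stats::setNames(integer(0), character(0)))
  counts <- table(all_labels)
  counts <- counts[order(-counts, names(counts))]
  stats::setNames(as.integer(counts), names(counts))
}
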