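#' Mutation rate of a gene within a sample set
#'
#' @param cohort A `CohortDataset` with a mutation indicator matrix.
#' @param sample_ids Sample identifiers (must be cohort samples).
#' @param gene Gene identifier.
#' @return Fraction of the samples with the gene mutated, or `NA` when the
#'   gene is absent from the cohort's mutation universe.
#' @export
mutation_rate <- function(cohort, sample_ids, gene) {
  if (length(sample_ids) == 0L) stop("sample_ids must be non-empty")
  if (is.null(cohort$mutated)) stop("cohort has no mutation layer")
  if (!all(sample_ids %in% colnames(cohort$mutated)))
    stop("sample_ids outside the cohort's mutation layer")
  if (!gene %in% rownames(cohort$mutated)) return(NA_real_)
  sum(cohort$mutated[gene, sample_ids]) / length(sample_ids)
}

#' Per-gene mutation-rate delta between high and low focal-expression groups
#'
#' Stratifies the cohort by [quartile_groups()] on the focal gene's
#' expression, then for each gene computes `delta = rate_high - rate_low`.
#' The positive/negative/unchanged status uses exact integer-count
#' comparison (cross-multiplication), so no floating-point tolerance enters
#' the sign; genes absent from the mutation universe get status `unknown`
#' with missing rates.
#'
#' @param cohort A `CohortDataset`.
#' @param focal_gene Focal gene identifier.
#' @param gene_list Genes to evaluate (e.g. a driver list).
#' @param groups Optional precomputed `StratifiedGroups`; defaults to
#'   quartile stratification on the focal gene.
#' @return data.frame of `DeltaRecord`s: `gene`, `cohort_id`, `rate_high`,
#'   `rate_low`, `delta`, `status`.
#' @export
delta_enrichment <- function(cohort, focal_gene, gene_list, groups = NULL) {
  if (is.null(groups))
    groups <- quartile_groups(gene_expression(cohort, focal_gene))
  m <- cohort$mutated
  if (is.null(m)) stop("cohort has no mutation layer")
  n_high <- length(groups$high_ids)
  n_low <- length(groups$low_ids)
  known <- gene_list %in% rownames(m)
  count_high <- count_low <- rep(NA_integer_, length(gene_list))
  if (any(known)) {
    sub_h <- m[gene_list[known], groups$high_ids, drop = FALSE]
    sub_l <- m[gene_list[known], groups$low_ids, drop = FALSE]
    count_high[known] <- as.integer(rowSums(sub_h))
    count_low[known] <- as.integer(rowSums(sub_l))
  }
  # sign via integer cross-multiplication: exact even when rates tie
  cross <- count_high * n_low - count_low * n_high
  status <- ifelse(!known, "unknown",
                   ifelse(cross > 0, "positive",
                          ifelse(cross < 0, "negative", "unchanged")))
  data.frame(gene = gene_list, cohort_id = cohort$cohort_id,
             rate_high = count_high / n_high, rate_low = count_low / n_low,
             delta = (count_high / n_high) - (count_low / n_low),
             status = status, stringsAsFactors = FALSE)
}

#' Cross-tumour-type pos/neg ratio classification for one gene
#'
#' Tallies a gene's delta statuses over tumour types (unknown records are
#' excluded from the ratio but counted). The ratio is `n_pos / n_neg`,
#' `+Inf` when `n_neg = 0` with `n_pos > 0`, and undefined (classified
#' `neither`) when both are 0. Classification: `enriched` iff ratio > 2,
#' `depleted` iff ratio <= 0.8, else `neither` (boundaries exact: 2.0 is
#' neither, 0.8 is depleted).
#'
#' @param records [delta_enrichment()] rows for a single gene across tumour
#'   types.
#' @return A `RatioSummary` one-row data.frame: `gene`, `n_pos`, `n_neg`,
#'   `n_unchanged`, `n_unknown`, `pos_neg_ratio`, `classification`.
#' @export
pos_neg_ratio <- function(records) {
  if (nrow(records) < 1L) stop("need >= 1 record")
  gene <- unique(records$gene)
  if (length(gene) != 1L) stop("records must cover a single gene")
  n_pos <- sum(records$status == "positive")
  n_neg <- sum(records$status == "negative")
  n_unchanged <- sum(records$status == "unchanged")
  n_unknown <- sum(records$status == "unknown")
  if (n_pos == 0L && n_neg == 0L) {
    ratio <- NA_real_
    cls <- "neither"
  } else {
    ratio <- if (n_neg == 0L) Inf else n_pos / n_neg
    # exact rational comparison: n_pos/n_neg > 2  <=>  n_pos > 2*n_neg
    cls <- if (n_pos > 2L * n_neg) "enriched"
           else if (5L * n_pos <= 4L * n_neg) "depleted"   # ratio <= 0.8
           else "neither"
  }
  data.frame(gene = gene, n_pos = n_pos, n_neg = n_neg,
             n_unchanged = n_unchanged, n_unknown = n_unknown,
             pos_neg_ratio = ratio, classification = cls,
             stringsAsFactors = FALSE)
}

#' Summarise pos/neg ratios for every gene in a delta-record table
#'
#' @param records Row-bound [delta_enrichment()] output across tumour types.
#' @return data.frame with one [pos_neg_ratio()] row per gene.
#' @export
summarise_ratios <- function(records) {
  out <- do.call(rbind, lapply(split(records, records$gene), pos_neg_ratio))
  rownames(out) <- NULL
  out[order(out$gene), , drop = FALSE]
}

#' Encode delta statuses as a gene x tumour-type integer matrix
#'
#' Status codes: positive = 1, negative = 2, unchanged = 3, unknown = 4
#' (missing grid cells are unknown). Rows are ordered by the number of
#' tumour types with positive enrichment, descending (ties alphabetical).
#'
#' @param records Row-bound [delta_enrichment()] output.
#' @return Integer matrix (genes x cohorts).
#' @export
encode_status_matrix <- function(records) {
  genes <- sort(unique(records$gene))
  cohorts <- sort(unique(records$cohort_id))
  codes <- c(positive = 1L, negative = 2L, unchanged = 3L, unknown = 4L)
  m <- matrix(4L, nrow = length(genes), ncol = length(cohorts),
              dimnames = list(genes, cohorts))
  m[cbind(match(records$gene, genes), match(records$cohort_id, cohorts))] <-
    codes[records$status]
  n_pos <- rowSums(m == 1L)
  m[order(-n_pos, rownames(m)), , drop = FALSE]
}

#' Decode a status matrix back to status labels
#'
#' Inverse of [encode_status_matrix()]'s code mapping.
#'
#' @param m Integer matrix with values in 1..4.
#' @return Character matrix of statuses.
#' @export
decode_status_matrix <- function(m) {
  labels <- c("positive", "negative", "unchanged", "unknown")
  out <- matrix(labels[m], nrow = nrow(m), dimnames = dimnames(m))
  out
}

#' Fraction of samples carrying an alteration of a given class in a gene
#'
#' @param cohort A `CohortDataset`.
#' @param alteration_class One of `"mutation"` (uses the mutation indicator)
#'   or the name of an extra alteration layer (e.g. `"amplification"`).
#' @param gene Gene identifier; defaults to the only gene in the layer when
#'   unambiguous.
#' @return Fraction of profiled samples with >= 1 alteration of that class.
#' @export
alteration_frequency <- function(cohort, alteration_class, gene = NULL) {
  layer <- if (identical(alteration_class, "mutation")) cohort$mutated
           else cohort$alterations[[alteration_class]]
  if (is.null(layer))
    stop(sprintf("alteration layer '%s' absent from cohort '%s'",
                 alteration_class, cohort$cohort_id))
  if (is.null(gene)) {
    if (nrow(layer) != 1L)
      stop("gene must be given when the layer holds multiple genes")
    gene <- rownames(layer)
  }
  if (!gene %in% rownames(layer))
    stop(sprintf("gene '%s' absent from alteration layer '%s'",
                 gene, alteration_class))
  mean(layer[gene, ])
}
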