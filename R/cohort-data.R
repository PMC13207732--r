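#' Cohort dataset container
#'
#' A `CohortDataset` bundles one cohort's molecular and clinical layers,
#' aligned on a master sample list (the columns of the expression matrix).
#'
#' @param cohort_id Single string identifying the cohort.
#' @param expression Numeric gene x sample matrix of non-negative,
#'   linear-scale abundances. Row names are gene identifiers (opaque,
#'   case-sensitive), column names are sample identifiers. `NA` cells are
#'   allowed and propagate pairwise into downstream statistics.
#' @param mutated Optional gene x sample binary (0/1) matrix; 1 means the
#'   gene carries at least one somatic mutation in that sample. Genes absent
#'   from this matrix have "unknown" mutation status downstream.
#' @param metrics Optional data.frame with a `sample_id` column and any of
#'   `mutation_count`, `fga`, `hrd_score`, `hypoxia_ragnum`, `hypoxia_winter`,
#'   `hypoxia_buffa`.
#' @param clinical Optional data.frame with a `sample_id` column and any of
#'   `t_stage` (one of `"T0".."T4"`), `grade` (`"low"`, `"mid"`, `"high"`),
#'   `os_time`, `os_event`, `pfs_time`, `pfs_event`.
#' @param alterations Optional named list of gene x sample binary matrices
#'   for additional alteration layers (e.g. `amplification`, `deletion`,
#'   `structural`).
#'
#' @return An object of class `CohortDataset`: a list with elements
#'   `cohort_id`, `expression`, `mutated`, `metrics`, `clinical`,
#'   `alterations` and `samples` (the master sample list).
#' @export
CohortDataset <- function(cohort_id, expression, mutated = NULL,
                          metrics = NULL, clinical = NULL,
                          alterations = NULL) {
  obj <- structure(
    list(
      cohort_id = cohort_id,
      expression = expression,
      mutated = mutated,
      metrics = metrics,
      clinical = clinical,
      alterations = alterations,
      samples = colnames(expression)
    ),
    class = "CohortDataset"
  )
  validate_cohort(obj)
  obj
}

#' Validate a CohortDataset against its invariants
#'
#' Checks sample alignment, value ranges (`fga` in \[0,1\], non-negative
#' mutation counts and survival times, binary event flags and mutation
#' indicators) and gene-identifier uniqueness. Errors on the first violation.
#'
#' @param x A `CohortDataset`.
#' @return `x`, invisibly, if valid.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "CohortDataset"))
  expr <- x$expression
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("expression must be a numeric matrix")
  if (ncol(expr) < 2L || nrow(expr) < 1L)
    stop("expression matrix needs >= 2 samples and >= 1 gene")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix must carry gene and sample names")
  if (anyDuplicated(rownames(expr)))
    stop("duplicate gene identifiers in expression matrix")
  if (anyDuplicated(colnames(expr)))
    stop("duplicate sample identifiers in expression matrix")
  if (any(expr < 0, na.rm = TRUE))
    stop("expression values must be non-negative")
  master <- colnames(expr)

  check_samples <- function(ids, layer) {
    if (!all(ids %in% master))
      stop(sprintf("%s contains samples outside the master sample list", layer))
  }
  if (!is.null(x$mutated)) {
    m <- x$mutated
    if (!is.matrix(m)) stop("mutated must be a matrix")
    check_samples(colnames(m), "mutated")
    if (anyDuplicated(rownames(m))) stop("duplicate genes in mutated matrix")
    if (!all(m %in% c(0, 1))) stop("mutated indicator must be 0/1")
  }
  if (!is.null(x$metrics)) {
    mt <- x$metrics
    if (!"sample_id" %in% names(mt)) stop("metrics needs a sample_id column")
    check_samples(mt$sample_id, "metrics")
    if (anyDuplicated(mt$sample_id)) stop("duplicate samples in metrics")
    if (!is.null(mt$mutation_count) &&
        any(mt$mutation_count < 0, na.rm = TRUE))
      stop("mutation_count must be >= 0")
    if (!is.null(mt$fga) &&
        any(mt$fga < 0 | mt$fga > 1, na.rm = TRUE))
      stop("fga must lie in [0,1]")
  }
  if (!is.null(x$clinical)) {
    cl <- x$clinical
    if (!"sample_id" %in% names(cl)) stop("clinical needs a sample_id column")
    check_samples(cl$sample_id, "clinical")
    if (anyDuplicated(cl$sample_id)) stop("duplicate samples in clinical")
    if (!is.null(cl$t_stage) &&
        !all(cl$t_stage %in% c(paste0("T", 0:4), NA)))
      stop("t_stage must be one of T0..T4")
    if (!is.null(cl$grade) &&
        !all(cl$grade %in% c("low", "mid", "high", NA)))
      stop("grade must be one of low/mid/high")
    for (tm in c("os_time", "pfs_time"))
      if (!is.null(cl[[tm]]) && any(cl[[tm]] < 0, na.rm = TRUE))
        stop(sprintf("%s must be >= 0", tm))
    for (ev in c("os_event", "pfs_event"))
      if (!is.null(cl[[ev]]) && !all(cl[[ev]] %in% c(0, 1, NA)))
        stop(sprintf("%s must be 0/1", ev))
  }
  if (!is.null(x$alterations)) {
    for (nm in names(x$alterations)) {
      a <- x$alterations[[nm]]
      check_samples(colnames(a), paste0("alterations$", nm))
      if (!all(a %in% c(0, 1)))
        stop(sprintf("alteration layer '%s' must be 0/1", nm))
    }
  }
  invisible(x)
}

#' @export
print.CohortDataset <- function(x, ...) {
  cat(sprintf("CohortDataset '%s': %d genes x %d samples\n",
              x$cohort_id, nrow(x$expression), ncol(x$expression)))
  layers <- c(
    if (!is.null(x$mutated))
      sprintf("mutation universe: %d genes", nrow(x$mutated)),
    if (!is.null(x$metrics))
      sprintf("metrics: %s",
              paste(setdiff(names(x$metrics), "sample_id"), collapse = ", ")),
    if (!is.null(x$clinical))
      sprintf("clinical: %s",
              paste(setdiff(names(x$clinical), "sample_id"), collapse = ", ")),
    if (!is.null(x$alterations))
      sprintf("alteration layers: %s",
              paste(names(x$alterations), collapse = ", "))
  )
  for (l in layers) cat(" ", l, "\n")
  invisible(x)
}

#' Fetch one gene's expression vector, aligned to the master sample list
#'
#' @param cohort A `CohortDataset`.
#' @param gene Gene identifier.
#' @return Named numeric vector over the cohort's samples.
#' @export
gene_expression <- function(cohort, gene) {
  if (!gene %in% rownames(cohort$expression))
    stop(sprintf("gene '%s' not found in cohort '%s'", gene, cohort$cohort_id))
  cohort$expression[gene, ]
}
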