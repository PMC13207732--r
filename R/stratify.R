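#' Quartile-based high/low stratification
#'
#' Thresholds are linear-interpolation empirical quantiles (type 7). By
#' default membership is inclusive (high: value >= 75th percentile; low:
#' value <= 25th percentile); `strict = TRUE` gives the exclusive variant.
#' Samples strictly between the two thresholds form the discarded middle.
#'
#' @param values Named numeric vector (names are sample identifiers).
#' @param high_q,low_q Quantile fractions for the high/low thresholds.
#' @param strict Use strict inequalities (> / <) for membership.
#' @return A `StratifiedGroups` list: `high_ids`, `low_ids`, `q_high`,
#'   `q_low`, `focal_values` (the non-missing input values).
#' @export
quartile_groups <- function(values, high_q = 0.75, low_q = 0.25,
                            strict = FALSE) {
  if (is.null(names(values))) stop("values must be named by sample")
  values <- values[!is.na(values)]
  if (length(values) < 8L)
    stop("need >= 8 non-missing values to stratify")
  qs <- stats::quantile(values, c(low_q, high_q), type = 7, names = FALSE)
  q_low <- qs[1L]; q_high <- qs[2L]
  if (q_high <= q_low)
    stop("degenerate stratification: quartile thresholds coincide")
  high <- if (strict) values > q_high else values >= q_high
  low <- if (strict) values < q_low else values <= q_low
  structure(list(high_ids = names(values)[high],
                 low_ids = names(values)[low],
                 q_high = q_high, q_low = q_low,
                 focal_values = values),
            class = "StratifiedGroups")
}

#' Within-cohort expression range (max/min ratio)
#'
#' @param values Numeric vector of strictly positive abundances.
#' @return max(values) / min(values).
#' @export
expression_range <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need >= 2 values")
  if (any(values <= 0))
    stop("expression range undefined for non-positive values")
  max(values) / min(values)
}

#' Two-sample rank-sum comparison of a continuous metric
#'
#' `mann_whitney` and `wilcoxon_ranksum` are aliases for the same unpaired
#' two-sample rank-sum computation (the underlying groups are independent in
#' every analysis this package performs). Small untied samples use the exact
#' enumeration; otherwise the tie-corrected normal approximation without
#' continuity correction is used, so identical groups give p = 1.
#'
#' @param high_values,low_values Numeric vectors (high group first, so the
#'   reported U statistic counts wins for the high group).
#' @param test Label recorded in the result.
#' @return A `TestResult` list: `test_name`, `statistic` (Mann-Whitney U for
#'   the high group), `p_value`, `n_high`, `n_low`.
#' @export
compare_continuous <- function(high_values, low_values,
                               test = c("mann_whitney", "wilcoxon_ranksum")) {
  test <- match.arg(test)
  high_values <- high_values[!is.na(high_values)]
  low_values <- low_values[!is.na(low_values)]
  if (length(high_values) == 0L || length(low_values) == 0L)
    stop("both groups must be non-empty")
  res <- suppressWarnings(
    stats::wilcox.test(high_values, low_values, correct = FALSE))
  structure(list(test_name = test,
                 statistic = unname(res$statistic),
                 p_value = min(1, res$p.value),
                 n_high = length(high_values),
                 n_low = length(low_values)),
            class = "TestResult")
}

#' Pearson chi-square test on a contingency table
#'
#' No continuity correction; df = (r-1)(c-1). Zero-marginal rows/columns are
#' dropped with a warning before testing.
#'
#' @param contingency r x c matrix of non-negative counts.
#' @return A `TestResult` list with `statistic`, `df`, `p_value` and the
#'   (possibly reduced) table as attribute `"table"`.
#' @export
compare_categorical <- function(contingency) {
  m <- as.matrix(contingency)
  if (any(m < 0)) stop("counts must be non-negative")
  keep_r <- rowSums(m) > 0
  keep_c <- colSums(m) > 0
  if (!all(keep_r) || !all(keep_c))
    warning("dropping zero-marginal row(s)/column(s)", call. = FALSE)
  m <- m[keep_r, keep_c, drop = FALSE]
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("contingency table needs >= 2 rows and >= 2 columns with positive marginals")
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  structure(list(test_name = "chi_square",
                 statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = res$p.value,
                 n_high = sum(m[1L, ]), n_low = sum(m[nrow(m), ])),
            class = "TestResult", table = m)
}

#' @export
print.TestResult <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %d vs %d)\n",
              x$test_name, x$statistic, x$p_value, x$n_high, x$n_low))
  invisible(x)
}

#' Compare molecular metrics between high and low focal-expression groups
#'
#' Runs the rank-sum comparison for each requested per-sample metric between
#' the high and low groups of `groups`.
#'
#' @param cohort A `CohortDataset` with a metrics table.
#' @param groups A `StratifiedGroups` object.
#' @param metrics Character vector of metric column names to compare.
#' @param test Passed to [compare_continuous()].
#' @return data.frame with one row per metric: `metric`, `statistic`,
#'   `p_value`, `n_high`, `n_low`, `median_high`, `median_low`.
#' @export
compare_metrics <- function(cohort, groups,
                            metrics = c("mutation_count", "fga", "hrd_score",
                                        "hypoxia_ragnum", "hypoxia_winter",
                                        "hypoxia_buffa"),
                            test = "mann_whitney") {
  mt <- cohort$metrics
  if (is.null(mt)) stop("cohort has no metrics table")
  metrics <- intersect(metrics, names(mt))
  rows <- lapply(metrics, function(nm) {
    hv <- mt[[nm]][mt$sample_id %in% groups$high_ids]
    lv <- mt[[nm]][mt$sample_id %in% groups$low_ids]
    hv <- hv[!is.na(hv)]; lv <- lv[!is.na(lv)]
    if (length(hv) == 0L || length(lv) == 0L) return(NULL)
    tr <- compare_continuous(hv, lv, test)
    data.frame(metric = nm, statistic = tr$statistic, p_value = tr$p_value,
               n_high = tr$n_high, n_low = tr$n_low,
               median_high = stats::median(hv), median_low = stats::median(lv),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
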