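#' Read a cBioPortal-style expression table
#'
#' Expects a tab-separated file whose first column holds gene identifiers and
#' whose remaining columns are samples; cells are numeric or empty (missing).
#'
#' @param path Path to the TSV file.
#' @return Numeric gene x sample matrix; empty cells become `NA`.
#' @export
read_expression_table <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expression table needs a gene column plus samples")
  genes <- raw[[1L]]
  if (anyDuplicated(genes))
    stop(sprintf("duplicate gene identifier(s): %s",
                 paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  cells[cells == ""] <- NA_character_
  suppressWarnings(num <- matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(num) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "non-numeric cell '%s' at gene row %d (%s), sample column %d (%s)",
      cells[bad[1, 1], bad[1, 2]], bad[1, 1], genes[bad[1, 1]],
      bad[1, 2], colnames(cells)[bad[1, 2]]))
  }
  dimnames(num) <- list(genes, colnames(cells))
  num
}

#' Read a long-format mutation table into a binary indicator matrix
#'
#' The table must carry `sample_id`, `gene` and `variant_class` columns (one
#' row per call). The indicator is 1 iff at least one retained row exists for
#' the (gene, sample) pair. Genes never mentioned are included as all-zero
#' rows only when listed in `gene_universe`; otherwise they are absent and
#' read as "unknown" downstream.
#'
#' @param path Path to the TSV file.
#' @param samples Character vector of sample identifiers defining the columns.
#' @param gene_universe Optional character vector of genes with known (possibly
#'   all-zero) mutation status.
#' @param include_classes Optional character vector of variant classes to
#'   retain (e.g. `c("missense", "insertion", "deletion", "frameshift")`);
#'   `NULL` keeps every class.
#' @return Binary gene x sample matrix.
#' @export
read_mutation_table <- function(path, samples, gene_universe = NULL,
                                include_classes = NULL) {
  tab <- utils::read.delim(path, colClasses = "character",
                           stringsAsFactors = FALSE)
  required <- c("sample_id", "gene", "variant_class")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L)
    stop(sprintf("mutation table missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  if (!is.null(include_classes))
    tab <- tab[tab$variant_class %in% include_classes, , drop = FALSE]
  tab <- tab[tab$sample_id %in% samples, , drop = FALSE]
  genes <- sort(unique(c(tab$gene, gene_universe)))
  ind <- matrix(0, nrow = length(genes), ncol = length(samples),
                dimnames = list(genes, samples))
  if (nrow(tab) > 0L)
    ind[cbind(match(tab$gene, genes), match(tab$sample_id, samples))] <- 1
  ind
}

#' Read one named gene set from a GMT file
#'
#' @param path Path to a GMT file (name, description, then members, all
#'   tab-separated, one set per line).
#' @param set_name Name of the set to extract.
#' @return A `GeneSet`: list with `name` and a de-duplicated character vector
#'   `genes`.
#' @export
read_gene_set_gmt <- function(path, set_name) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  names(fields) <- vapply(fields, `[`, "", 1L)
  if (!set_name %in% names(fields))
    stop(sprintf("gene set '%s' not found in %s", set_name, path))
  members <- fields[[set_name]][-(1:2)]
  members <- unique(members[nzchar(members)])
  if (length(members) == 0L)
    stop(sprintf("gene set '%s' is empty", set_name))
  structure(list(name = set_name, genes = members), class = "GeneSet")
}

#' Read a one-gene-per-line driver list
#'
#' @param path Path to a plain-text file, one gene identifier per line.
#' @return Character vector of unique gene identifiers.
#' @export
read_driver_list <- function(path) {
  genes <- trimws(readLines(path, warn = FALSE))
  unique(genes[nzchar(genes)])
}

#' Read a per-sample table (metrics or clinical) keyed by sample_id
#'
#' @param path Path to a TSV with a `sample_id` column.
#' @return data.frame; numeric-looking columns are converted to numeric.
#' @export
read_sample_table <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(tab))
    stop("per-sample table needs a sample_id column")
  for (nm in setdiff(names(tab), "sample_id")) {
    v <- tab[[nm]]
    v[v == ""] <- NA_character_
    suppressWarnings(num <- as.numeric(v))
    tab[[nm]] <- if (all(is.na(num) == is.na(v))) num else v
  }
  tab
}

#' Assemble aligned cohort layers into a CohortDataset
#'
#' The master sample list is the expression matrix's columns; every other
#' layer is restricted and re-ordered to it. Samples present in a secondary
#' layer but not in the expression matrix are dropped with a warning.
#'
#' @param expression Gene x sample numeric matrix.
#' @param mutated Optional binary gene x sample matrix.
#' @param metrics,clinical Optional data.frames with `sample_id`.
#' @param cohort_id Cohort identifier string.
#' @param alterations Optional named list of binary matrices.
#' @return A validated `CohortDataset`.
#' @export
assemble_cohort <- function(expression, mutated = NULL, metrics = NULL,
                            clinical = NULL, cohort_id = "cohort",
                            alterations = NULL) {
  master <- colnames(expression)
  if (length(master) < 2L)
    stop("fewer than 2 samples in the expression matrix")

  align_matrix <- function(m, layer) {
    keep <- intersect(master, colnames(m))
    dropped <- setdiff(colnames(m), master)
    if (length(dropped) > 0L)
      warning(sprintf("%s: dropped %d sample(s) absent from expression",
                      layer, length(dropped)), call. = FALSE)
    if (length(keep) < 2L)
      stop(sprintf("%s shares fewer than 2 samples with expression", layer))
    m[, keep, drop = FALSE]
  }
  align_table <- function(tab, layer) {
    dropped <- setdiff(tab$sample_id, master)
    if (length(dropped) > 0L)
      warning(sprintf("%s: dropped %d sample(s) absent from expression",
                      layer, length(dropped)), call. = FALSE)
    tab <- tab[tab$sample_id %in% master, , drop = FALSE]
    if (nrow(tab) < 2L)
      stop(sprintf("%s shares fewer than 2 samples with expression", layer))
    tab[order(match(tab$sample_id, master)), , drop = FALSE]
  }

  if (!is.null(mutated)) mutated <- align_matrix(mutated, "mutated")
  if (!is.null(metrics)) metrics <- align_table(metrics, "metrics")
  if (!is.null(clinical)) clinical <- align_table(clinical, "clinical")
  if (!is.null(alterations))
    alterations <- lapply(stats::setNames(names(alterations),
                                          names(alterations)),
                          function(nm) align_matrix(alterations[[nm]],
                                                    paste0("alterations$", nm)))
  expression <- expression[order(rownames(expression)), , drop = FALSE]
  if (!is.null(mutated))
    mutated <- mutated[order(rownames(mutated)), , drop = FALSE]
  if (!is.null(metrics)) rownames(metrics) <- NULL
  if (!is.null(clinical)) rownames(clinical) <- NULL
  CohortDataset(cohort_id, expression, mutated, metrics, clinical, alterations)
}

#' Write a gene x sample matrix as TSV
#'
#' Inverse of [read_expression_table()]: first column `gene`, then one column
#' per sample. Full precision (15 significant digits) so that decimal-
#' representable values round-trip exactly.
#'
#' @param mat Matrix with row and column names.
#' @param path Output path.
#' @param id_col Name for the first (identifier) column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(mat, path, id_col = "gene") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  write_result_table(df, path)
}

#' Write a result table as TSV with fixed column order
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path) {
  for (nm in names(df))
    if (is.numeric(df[[nm]]))
      df[[nm]] <- formatC(df[[nm]], digits = 15, format = "g")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' The configuration is a Debian-control-style (DCF) text file with one block
#' per cohort plus a header block. The header block carries `focal_gene` and
#' optionally `gene_set_gmt`, `gene_set_name`, `driver_list`; each cohort
#' block carries `cohort_id`, `expression` and optionally `mutations`,
#' `metrics`, `clinical` file paths (relative paths are resolved against the
#' config file's directory).
#'
#' @param path Path to the config file.
#' @return List with `focal_gene`, optional resource paths, and a list
#'   `cohorts` of per-cohort path sets.
#' @export
read_config <- function(path) {
  blocks <- read.dcf(path)
  base <- dirname(path)
  resolve <- function(p) ifelse(is.na(p) | grepl("^/", p), p,
                                file.path(base, p))
  blocks <- as.data.frame(blocks, stringsAsFactors = FALSE)
  header_row <- which(!is.na(blocks$focal_gene))
  if (length(header_row) != 1L)
    stop("config must contain exactly one block with focal_gene")
  header <- blocks[header_row, , drop = FALSE]
  cohort_rows <- blocks[-header_row, , drop = FALSE]
  cohorts <- lapply(seq_len(nrow(cohort_rows)), function(i) {
    row <- cohort_rows[i, , drop = FALSE]
    if (is.na(row$cohort_id) || is.na(row$expression))
      stop("each cohort block needs cohort_id and expression")
    list(cohort_id = row$cohort_id,
         expression = resolve(row$expression),
         mutations = if ("mutations" %in% names(row)) resolve(row$mutations),
         metrics = if ("metrics" %in% names(row)) resolve(row$metrics),
         clinical = if ("clinical" %in% names(row)) resolve(row$clinical))
  })
  list(focal_gene = header$focal_gene,
       gene_set_gmt = if ("gene_set_gmt" %in% names(header))
         resolve(header$gene_set_gmt),
       gene_set_name = if ("gene_set_name" %in% names(header))
         header$gene_set_name,
       driver_list = if ("driver_list" %in% names(header))
         resolve(header$driver_list),
       cohorts = cohorts)
}
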