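#' Validate an expression matrix
#'
#' The classifier consumes a numeric genes-by-samples matrix of normalized
#' expression. Because every downstream step is rank-based, any
#' monotone-consistent per-sample scale (log2 intensities, log-CPM, VST, ...)
#' is acceptable; no normalization is performed here. Requirements: unique
#' non-empty gene rownames, unique sample colnames, all values finite, at
#' least 2 genes and 1 sample.
#'
#' @param expr Numeric matrix, genes in rows, samples in columns.
#' @return `expr`, invisibly, after validation.
#' @export
validate_expression_matrix <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    rlang::abort("expression must be a numeric matrix (genes x samples)")
  }
  if (nrow(expr) < 2 || ncol(expr) < 1) {
    rlang::abort("expression matrix needs at least 2 genes and 1 sample")
  }
  g <- rownames(expr)
  s <- colnames(expr)
  if (is.null(g) || any(!nzchar(g))) {
    rlang::abort("expression matrix must have non-empty gene rownames")
  }
  if (anyDuplicated(g)) {
    rlang::abort(sprintf(
      "duplicate gene id(s): %s",
      paste(unique(g[duplicated(g)]), collapse = ", ")
    ))
  }
  if (is.null(s) || any(!nzchar(s))) {
    rlang::abort("expression matrix must have non-empty sample colnames")
  }
  if (anyDuplicated(s)) {
    rlang::abort(sprintf(
      "duplicate sample id(s): %s",
      paste(unique(s[duplicated(s)]), collapse = ", ")
    ))
  }
  if (!all(is.finite(expr))) {
    bad <- which(!is.finite(expr), arr.ind = TRUE)[1, ]
    rlang::abort(sprintf(
      "non-finite expression value at gene '%s', sample '%s'",
      g[bad[1]], s[bad[2]]
    ))
  }
  invisible(expr)
}

#' Read a genes-by-samples expression matrix from TSV
#'
#' Expects a header row of sample names and a first column of gene symbols.
#' Duplicate gene rows and non-numeric or missing cells are errors with a
#' location; nothing is silently dropped or collapsed.
#'
#' @param path Path to a tab-separated file.
#' @return A numeric matrix with gene rownames and sample colnames.
#' @seealso [write_expression_matrix()]
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("expression file not found: %s", path))
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2) {
    rlang::abort(sprintf("expression file %s has no sample columns", path))
  }
  genes <- df[[1]]
  samples <- colnames(df)[-1]
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    rlang::abort(sprintf(
      "non-numeric or non-finite cell '%s' at gene '%s' (row %d), sample '%s' in %s",
      vals[bad[1, 1], bad[1, 2]], genes[bad[1, 1]], bad[1, 1] + 1L,
      samples[bad[1, 2]], path
    ))
  }
  dimnames(num) <- list(genes, samples)
  validate_expression_matrix(num)
  num
}

#' Write an expression matrix to TSV
#'
#' @param expr Numeric genes-by-samples matrix.
#' @param path Output path.
#' @param gene_column Name of the first (gene id) column in the header.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path, gene_column = "gene_id") {
  validate_expression_matrix(expr)
  df <- data.frame(rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- gene_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a subtype label table
#'
#' Two-column TSV with a header (`sample_id`, `subtype`); every subtype must
#' be one of [mb_subtypes()].
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `sample_id` (character) and `subtype`
#'   (factor over [mb_subtypes()]).
#' @seealso [write_labels()]
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("label file not found: %s", path))
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  if (ncol(df) != 2) {
    rlang::abort(sprintf("label file %s must have exactly 2 columns", path))
  }
  if (anyDuplicated(df[[1]])) {
    rlang::abort(sprintf(
      "duplicate sample id(s) in %s: %s", path,
      paste(unique(df[[1]][duplicated(df[[1]])]), collapse = ", ")
    ))
  }
  tibble::tibble(
    sample_id = df[[1]],
    subtype = as_subtype_factor(df[[2]], what = "subtype")
  )
}

#' Write a subtype label table
#'
#' @param labels Tibble/data frame with columns `sample_id` and `subtype`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  stopifnot(all(c("sample_id", "subtype") %in% colnames(labels)))
  as_subtype_factor(labels$subtype)
  utils::write.table(
    data.frame(sample_id = labels$sample_id,
               subtype = as.character(labels$subtype)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read a mouse-to-human ortholog map
#'
#' Two-column TSV with a header (`mouse`, `human`): mouse gene symbol to its
#' human ortholog symbol. Supports users who hold one species' GMT and need
#' to translate member genes for the paired species; the classifier itself
#' never translates genes at predict time (cross-species harmonization works
#' on shared term names).
#'
#' @param path Path to the TSV.
#' @return A tibble with character columns `mouse` and `human`.
#' @export
read_ortholog_map <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("ortholog map not found: %s", path))
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  if (ncol(df) != 2) {
    rlang::abort(sprintf("ortholog map %s must have exactly 2 columns", path))
  }
  if (anyDuplicated(df[[1]])) {
    rlang::abort(sprintf("duplicate mouse symbol(s) in %s", path))
  }
  if (any(!nzchar(df[[1]])) || any(!nzchar(df[[2]]))) {
    rlang::abort(sprintf("empty gene symbol in %s", path))
  }
  tibble::tibble(mouse = df[[1]], human = df[[2]])
}

#' Write an ortholog map
#'
#' @param map Tibble with character columns `mouse` and `human`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ortholog_map <- function(map, path) {
  stopifnot(all(c("mouse", "human") %in% colnames(map)))
  utils::write.table(map[, c("mouse", "human")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

prediction_columns <- function() {
  c("sample_id", "predicted_subtype", "confidence_percent",
    paste0("vote_", mb_subtypes()), "call_class")
}

#' Write a prediction table
#'
#' Columns: `sample_id`, `predicted_subtype`, `confidence_percent` (0-100),
#' one `vote_<subtype>` integer neighbour count per class, and `call_class`
#' (`high_confidence` when the winning vote fraction is at least 80%,
#' `intermediate` otherwise).
#'
#' @param results A predictions tibble from [classify_human()] /
#'   [classify_mouse()] or [read_predictions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(results, path) {
  missing <- setdiff(prediction_columns(), colnames(results))
  if (length(missing) > 0) {
    rlang::abort(sprintf(
      "prediction table is missing column(s): %s", paste(missing, collapse = ", ")
    ))
  }
  df <- as.data.frame(results[, prediction_columns()])
  df$predicted_subtype <- as.character(df$predicted_subtype)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a prediction table
#'
#' @param path Path written by [write_predictions()].
#' @return A tibble with the columns described in [write_predictions()].
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("prediction file not found: %s", path))
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  missing <- setdiff(prediction_columns(), colnames(df))
  if (length(missing) > 0) {
    rlang::abort(sprintf(
      "prediction file %s is missing column(s): %s",
      path, paste(missing, collapse = ", ")
    ))
  }
  out <- tibble::as_tibble(df[, prediction_columns()])
  out$predicted_subtype <- as_subtype_factor(out$predicted_subtype,
                                             what = "predicted_subtype")
  out$confidence_percent <- as.numeric(out$confidence_percent)
  for (v in paste0("vote_", mb_subtypes())) out[[v]] <- as.integer(out[[v]])
  bad <- setdiff(unique(out$call_class), c("high_confidence", "intermediate"))
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "invalid call_class value(s) in %s: %s", path, paste(bad, collapse = ", ")
    ))
  }
  out
}
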