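#' Rank gene sets within each sample by descending enrichment
#'
#' Converts enrichment scores to the classifier's feature space: within each
#' sample, the gene set with the highest ES gets rank 1, ties receive the
#' average rank. Ranks are computed over (and restricted to) `geneset_subset`
#' only, because a rank is only meaningful within a fixed gene-set universe.
#'
#' @param es Genesets-by-samples enrichment matrix from [ssgsea()].
#' @param geneset_subset Character vector of gene-set names to rank over;
#'   default all rows of `es`.
#' @return A samples-by-genesets numeric matrix of tie-averaged descending
#'   ranks (each row sums to n(n+1)/2 for n gene sets).
#' @export
rank_transform <- function(es, geneset_subset = rownames(es)) {
  stopifnot(is.matrix(es))
  geneset_subset <- as.character(geneset_subset)
  if (length(geneset_subset) == 0) {
    rlang::abort("geneset_subset is empty")
  }
  missing <- setdiff(geneset_subset, rownames(es))
  if (length(missing) > 0) {
    rlang::abort(sprintf(
      "geneset(s) not in enrichment matrix: %s", paste(missing, collapse = ", ")
    ))
  }
  sub <- es[geneset_subset, , drop = FALSE]
  out <- apply(sub, 2, function(col) rank(-col, ties.method = "average"))
  # apply() returns genesets x samples; KNN wants samples in rows
  out <- t(matrix(out, nrow = length(geneset_subset),
                  dimnames = list(geneset_subset, colnames(es))))
  out
}

#' Select subtype-discriminative gene sets
#'
#' Scores each gene set's between-class separation of enrichment scores and
#' returns the `n_top` most discriminative set names. The default statistic
#' is the Kruskal-Wallis H across subtype classes -- a distribution-free,
#' rank-based choice consistent with the rank-based pipeline. Gene sets with
#' identical ES in all samples score 0. Ties in the statistic are broken by
#' gene-set name, making selection deterministic.
#'
#' @param es Genesets-by-samples enrichment matrix.
#' @param labels Tibble with columns `sample_id`, `subtype` covering every
#'   sample of `es`; at least 2 classes must be present.
#' @param n_top Number of gene sets to keep (error if more than available).
#' @return Character vector of `n_top` gene-set names, ordered by decreasing
#'   discriminative statistic.
#' @export
select_discriminative_genesets <- function(es, labels, n_top = 100) {
  stopifnot(is.matrix(es), n_top >= 1)
  cls <- label_vector(labels, colnames(es))
  if (length(unique(cls)) < 2) {
    rlang::abort("at least 2 subtype classes are required for selection")
  }
  if (n_top > nrow(es)) {
    rlang::abort(sprintf(
      "n_top = %d exceeds the %d available genesets", n_top, nrow(es)
    ))
  }
  grp <- factor(cls[colnames(es)])
  stat <- apply(es, 1, function(v) {
    if (length(unique(v)) == 1L) return(0)
    unname(stats::kruskal.test(v, grp)$statistic)
  })
  ord <- order(-stat, rownames(es))
  rownames(es)[ord][seq_len(n_top)]
}

# labels tibble -> named character vector covering sample_ids (error listing
# the missing samples otherwise)
label_vector <- function(labels, sample_ids) {
  stopifnot(all(c("sample_id", "subtype") %in% colnames(labels)))
  lv <- stats::setNames(as.character(labels$subtype), labels$sample_id)
  as_subtype_factor(labels$subtype)
  missing <- setdiff(sample_ids, names(lv))
  if (length(missing) > 0) {
    rlang::abort(sprintf(
      "sample(s) without a subtype label: %s", paste(missing, collapse = ", ")
    ))
  }
  lv[sample_ids]
}

#' Build a training reference for subtype prediction
#'
#' Runs the full training pipeline on a labelled cohort: ssGSEA over the
#' gene-set collection, selection of the most subtype-discriminative gene
#' sets, and the per-sample descending-ES rank transform. The resulting
#' reference stores everything prediction needs -- the rank matrix, labels
#' and hyperparameters -- without the original expression data, so any
#' labelled cohort can serve as the reference.
#'
#' @param expr Numeric genes-by-samples expression matrix of the cohort.
#' @param labels Tibble (`sample_id`, `subtype`) labelling every sample.
#' @param collection A [gene_set_collection()] (typically human GO BP sets).
#' @param k Neighbour count for prediction; default 5; must not exceed the
#'   cohort size.
#' @param n_top Number of discriminative gene sets to keep (default 100).
#' @param alpha ssGSEA rank-weight exponent (default 0.25).
#' @param es_mode `"integrated"` or `"max"` (see [enrichment_score()]).
#' @param metric KNN distance on rank vectors, `"euclidean"` (default) or
#'   `"manhattan"`.
#' @param provenance Free-text note stored with the reference.
#' @return An object of class `mb_reference`.
#' @seealso [classify_human()], [save_reference()], [tidy.mb_reference()]
#' @export
build_reference <- function(expr, labels, collection, k = 5, n_top = 100,
                            alpha = 0.25, es_mode = c("integrated", "max"),
                            metric = c("euclidean", "manhattan"),
                            provenance = "") {
  es_mode <- match.arg(es_mode)
  metric <- match.arg(metric)
  stopifnot(k >= 1)
  cls <- label_vector(labels, colnames(expr))
  if (k > ncol(expr)) {
    rlang::abort(sprintf(
      "k = %d exceeds the %d reference samples", k, ncol(expr)
    ))
  }
  es <- ssgsea(expr, collection, alpha = alpha, es_mode = es_mode)
  selected <- select_discriminative_genesets(es, labels, n_top = n_top)
  rank_matrix <- rank_transform(es, selected)
  new_mb_reference(
    geneset_names = selected,
    rank_matrix = rank_matrix,
    labels = factor(as.character(cls), levels = mb_subtypes()),
    hyperparams = list(
      alpha = alpha, k = as.integer(k), n_top = as.integer(n_top),
      es_mode = es_mode, metric = metric,
      selection_statistic = "kruskal_wallis"
    ),
    provenance = provenance
  )
}

reference_format_version <- 1L

new_mb_reference <- function(geneset_names, rank_matrix, labels, hyperparams,
                             provenance = "") {
  stopifnot(
    is.matrix(rank_matrix),
    identical(colnames(rank_matrix), geneset_names),
    length(labels) == nrow(rank_matrix)
  )
  names(labels) <- rownames(rank_matrix)
  if (length(unique(labels)) < 2) {
    rlang::abort("reference labels must cover at least 2 distinct classes")
  }
  if (hyperparams$k > nrow(rank_matrix)) {
    rlang::abort("k exceeds the number of reference samples")
  }
  structure(
    list(
      geneset_names = geneset_names,
      rank_matrix = rank_matrix,
      labels = labels,
      hyperparams = hyperparams,
      provenance = provenance,
      version = reference_format_version
    ),
    class = "mb_reference"
  )
}

#' @export
print.mb_reference <- function(x, ...) {
  cat(sprintf(
    "<mb_reference> %d samples x %d genesets | classes: %s\n",
    nrow(x$rank_matrix), length(x$geneset_names),
    paste(sprintf("%s=%d", names(table(droplevels(x$labels))),
                  table(droplevels(x$labels))), collapse = ", ")
  ))
  h <- x$hyperparams
  cat(sprintf(
    "  alpha=%g k=%d n_top=%d es_mode=%s metric=%s selection=%s\n",
    h$alpha, h$k, h$n_top, h$es_mode, h$metric, h$selection_statistic
  ))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Save a training reference to a versioned text archive
#'
#' The archive is a single self-describing tab-separated text file:
#' a magic/version header, a `[hyperparams]` key-value block, a
#' `[provenance]` line, a `[labels]` table and the `[rank_matrix]` table.
#' Diffable and language-neutral; [load_reference()] is its exact inverse.
#'
#' @param ref An `mb_reference`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_reference <- function(ref, path) {
  stopifnot(inherits(ref, "mb_reference"))
  h <- ref$hyperparams
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("#mbsubtyper_reference\t%d", ref$version), con)
  writeLines("[hyperparams]", con)
  writeLines(sprintf("%s\t%s", names(h), vapply(h, function(v)
    format(v, digits = 17), "")), con)
  writeLines("[provenance]", con)
  writeLines(gsub("\n", "\\\\n", ref$provenance), con)
  writeLines("[labels]", con)
  writeLines("sample_id\tsubtype", con)
  writeLines(sprintf("%s\t%s", names(ref$labels), as.character(ref$labels)), con)
  writeLines("[rank_matrix]", con)
  writeLines(paste(c("sample_id", ref$geneset_names), collapse = "\t"), con)
  writeLines(vapply(seq_len(nrow(ref$rank_matrix)), function(i) {
    paste(c(rownames(ref$rank_matrix)[i],
            format(ref$rank_matrix[i, ], digits = 17, trim = TRUE)),
          collapse = "\t")
  }, ""), con)
  invisible(path)
}

#' Load a training reference saved by [save_reference()]
#'
#' A missing section, truncated file or unknown format version is an
#' explicit error; the file is never silently reinterpreted.
#'
#' @param path Path to the archive.
#' @return An `mb_reference`.
#' @export
load_reference <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("reference file not found: %s", path))
  }
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 1 || !startsWith(lines[1], "#mbsubtyper_reference")) {
    rlang::abort(sprintf("%s is not a mbsubtyper reference archive", path))
  }
  ver <- suppressWarnings(as.integer(strsplit(lines[1], "\t")[[1]][2]))
  if (is.na(ver) || ver != reference_format_version) {
    rlang::abort(sprintf(
      "unsupported reference format version '%s' in %s (this build reads version %d)",
      strsplit(lines[1], "\t")[[1]][2], path, reference_format_version
    ))
  }
  section_at <- function(tag) {
    i <- which(lines == tag)
    if (length(i) != 1) {
      rlang::abort(sprintf("reference archive %s: missing section %s", path, tag))
    }
    i
  }
  i_h <- section_at("[hyperparams]")
  i_p <- section_at("[provenance]")
  i_l <- section_at("[labels]")
  i_r <- section_at("[rank_matrix]")
  if (!(i_h < i_p && i_p < i_l && i_l < i_r && i_r < length(lines))) {
    rlang::abort(sprintf("reference archive %s is truncated or out of order", path))
  }

  kv <- strsplit(lines[(i_h + 1):(i_p - 1)], "\t", fixed = TRUE)
  h <- stats::setNames(purrr::map_chr(kv, 2), purrr::map_chr(kv, 1))
  needed <- c("alpha", "k", "n_top", "es_mode", "metric", "selection_statistic")
  if (!all(needed %in% names(h))) {
    rlang::abort(sprintf(
      "reference archive %s: missing hyperparameter(s) %s",
      path, paste(setdiff(needed, names(h)), collapse = ", ")
    ))
  }
  hyper <- list(
    alpha = as.numeric(h[["alpha"]]), k = as.integer(h[["k"]]),
    n_top = as.integer(h[["n_top"]]), es_mode = h[["es_mode"]],
    metric = h[["metric"]], selection_statistic = h[["selection_statistic"]]
  )
  provenance <- gsub("\\\\n", "\n", paste(lines[(i_p + 1):(i_l - 1)],
                                          collapse = ""))

  lab_lines <- lines[(i_l + 2):(i_r - 1)]
  lab_f <- strsplit(lab_lines, "\t", fixed = TRUE)
  labels <- as_subtype_factor(purrr::map_chr(lab_f, 2))
  names(labels) <- purrr::map_chr(lab_f, 1)

  header <- strsplit(lines[i_r + 1], "\t", fixed = TRUE)[[1]]
  genesets <- header[-1]
  row_lines <- lines[(i_r + 2):length(lines)]
  row_f <- strsplit(row_lines, "\t", fixed = TRUE)
  if (any(lengths(row_f) != length(header))) {
    rlang::abort(sprintf("reference archive %s: ragged rank_matrix rows", path))
  }
  rank_matrix <- do.call(rbind, purrr::map(row_f, ~ as.numeric(.x[-1])))
  dimnames(rank_matrix) <- list(purrr::map_chr(row_f, 1), genesets)
  if (!all(is.finite(rank_matrix))) {
    rlang::abort(sprintf("reference archive %s: non-numeric rank values", path))
  }
  if (!setequal(names(labels), rownames(rank_matrix))) {
    rlang::abort(sprintf("reference archive %s: labels and rank matrix disagree", path))
  }
  new_mb_reference(
    geneset_names = genesets, rank_matrix = rank_matrix,
    labels = labels[rownames(rank_matrix)], hyperparams = hyper,
    provenance = provenance
  )
}
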