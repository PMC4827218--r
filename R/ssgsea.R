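#' Rank the genes of one sample
#'
#' First step of single-sample gene set enrichment analysis: within one
#' sample, genes are ranked by expression so that the highest-expressed gene
#' carries the largest rank value (G for G genes), with tied expression
#' values receiving the average of their ranks. Because only ranks are used
#' downstream, the whole pipeline is invariant to any strictly increasing
#' per-sample transform of expression.
#'
#' @param expr Numeric genes-by-samples expression matrix.
#' @param sample_id Name of the sample (column) to rank.
#' @return A list with `sample_id`, `gene_order` (gene names sorted by
#'   decreasing expression, ties kept in input order) and `rank_values`
#'   (named numeric vector of tie-averaged ranks, in input gene order).
#' @export
rank_genes <- function(expr, sample_id) {
  validate_expression_matrix(expr)
  if (!sample_id %in% colnames(expr)) {
    rlang::abort(sprintf("unknown sample '%s'", sample_id))
  }
  x <- expr[, sample_id]
  if (length(unique(x)) == 1L) {
    rlang::abort(sprintf(
      "sample '%s' has constant expression across all genes; ranking is undefined",
      sample_id
    ))
  }
  r <- rank(x, ties.method = "average")
  structure(
    list(
      sample_id = sample_id,
      gene_order = rownames(expr)[stable_desc_order(x)],
      rank_values = stats::setNames(r, rownames(expr))
    ),
    class = "ranked_profile"
  )
}

# Shared core: running-sum ES for one ranked profile and one gene set.
# Walk genes in decreasing-expression order; at each position i,
#   P_in(i)  = sum of r^alpha over set genes seen so far / total over the set
#   P_out(i) = count of non-set genes seen so far / (G - |set genes measured|)
# integrated mode sums P_in - P_out over all positions; max mode returns the
# running difference at its maximum absolute deviation (first such position).
es_running_sum <- function(rank_sorted, in_set_sorted, alpha, es_mode) {
  m <- sum(in_set_sorted)
  G <- length(rank_sorted)
  if (m == 0L) {
    rlang::abort("geneset has no measured genes")
  }
  if (m == G) {
    rlang::abort("geneset covers every measured gene; complement is empty")
  }
  w <- rank_sorted^alpha
  p_in <- cumsum(w * in_set_sorted) / sum(w[in_set_sorted])
  p_out <- cumsum(!in_set_sorted) / (G - m)
  d <- p_in - p_out
  if (es_mode == "integrated") sum(d) else d[which.max(abs(d))]
}

#' Enrichment score of one gene set in one sample
#'
#' The ssGSEA statistic: a weighted running-sum comparison of the empirical
#' distribution of set members against non-members along the sample's
#' decreasing-expression gene order. Set-member steps are weighted by the
#' gene's rank value raised to `alpha`; the default `es_mode = "integrated"`
#' sums the running difference over all positions (the ssGSEA variant), while
#' `"max"` takes the maximum-deviation value (the classic GSEA statistic).
#' Genes in the set that are not measured in the profile are ignored.
#'
#' @param profile A ranked profile from [rank_genes()].
#' @param gene_set Character vector of member gene symbols.
#' @param alpha Non-negative rank-weight exponent (default 0.25).
#' @param es_mode `"integrated"` (default) or `"max"`.
#' @return A single finite enrichment score.
#' @export
#' @examples
#' expr <- matrix(5:1, ncol = 1, dimnames = list(paste0("g", 1:5), "s1"))
#' expr <- cbind(expr, s2 = 1:5)
#' p <- rank_genes(expr, "s1")
#' enrichment_score(p, c("g1", "g3"), alpha = 0) # 5/3
enrichment_score <- function(profile, gene_set, alpha = 0.25,
                             es_mode = c("integrated", "max")) {
  es_mode <- match.arg(es_mode)
  stopifnot(inherits(profile, "ranked_profile"), alpha >= 0)
  r_sorted <- profile$rank_values[profile$gene_order]
  in_set <- profile$gene_order %in% gene_set
  es_running_sum(unname(r_sorted), in_set, alpha, es_mode)
}

#' Single-sample GSEA over a gene-set collection
#'
#' Computes the enrichment score of every gene set in every sample,
#' independently per sample. Gene sets with no measured member genes are
#' dropped with a warning (an error only if none survive); unmeasured member
#' genes within surviving sets are ignored, with counts reported via a
#' message when `verbose = TRUE`.
#'
#' @param expr Numeric genes-by-samples expression matrix.
#' @param collection A [gene_set_collection()].
#' @param alpha Rank-weight exponent, default 0.25.
#' @param es_mode `"integrated"` (default) or `"max"`.
#' @param verbose Report unmeasured-gene counts per set.
#' @return A numeric genesets-by-samples matrix of enrichment scores with
#'   attributes `alpha` and `es_mode`.
#' @export
ssgsea <- function(expr, collection, alpha = 0.25,
                   es_mode = c("integrated", "max"), verbose = FALSE) {
  es_mode <- match.arg(es_mode)
  validate_expression_matrix(expr)
  stopifnot(inherits(collection, "gene_set_collection"), alpha >= 0)

  universe <- rownames(expr)
  measured <- purrr::map(collection$genes, ~ intersect(.x, universe))
  n_meas <- lengths(measured)
  empty <- n_meas == 0L
  covers_all <- n_meas == length(universe)
  if (all(empty)) {
    rlang::abort("no geneset has any measured genes in this expression matrix")
  }
  if (any(empty)) {
    rlang::warn(sprintf(
      "dropping %d geneset(s) with no measured genes: %s",
      sum(empty), paste(collection$name[empty], collapse = ", ")
    ))
  }
  if (any(covers_all)) {
    rlang::abort(sprintf(
      "geneset(s) covering every measured gene: %s",
      paste(collection$name[covers_all], collapse = ", ")
    ))
  }
  keep <- which(!empty)
  if (verbose) {
    dropped_genes <- lengths(collection$genes[keep]) - n_meas[keep]
    message(sprintf(
      "ssgsea: %d/%d genesets kept; %d unmeasured member genes ignored",
      length(keep), nrow(collection), sum(dropped_genes)
    ))
  }

  es <- matrix(
    NA_real_, nrow = length(keep), ncol = ncol(expr),
    dimnames = list(collection$name[keep], colnames(expr))
  )
  for (s in colnames(expr)) {
    prof <- rank_genes(expr, s)
    r_sorted <- unname(prof$rank_values[prof$gene_order])
    w <- r_sorted^alpha
    for (j in seq_along(keep)) {
      in_set <- prof$gene_order %in% measured[[keep[j]]]
      p_in <- cumsum(w * in_set) / sum(w[in_set])
      p_out <- cumsum(!in_set) / (length(r_sorted) - sum(in_set))
      d <- p_in - p_out
      es[j, s] <- if (es_mode == "integrated") sum(d) else d[which.max(abs(d))]
    }
  }
  attr(es, "alpha") <- alpha
  attr(es, "es_mode") <- es_mode
  es
}

#' Enrichment matrix as a tibble
#'
#' Long-format view of an enrichment matrix, one row per (geneset, sample).
#'
#' @param es Matrix from [ssgsea()].
#' @return A tibble with columns `gene_set`, `sample_id`, `es`.
#' @export
tidy_enrichment <- function(es) {
  stopifnot(is.matrix(es))
  tibble::as_tibble(as.table(es), .name_repair = "minimal") |>
    stats::setNames(c("gene_set", "sample_id", "es")) |>
    dplyr::mutate(dplyr::across(c("gene_set", "sample_id"), as.character))
}
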