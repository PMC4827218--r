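#' Harmonize gene sets between a test enrichment matrix and a reference
#'
#' Test samples are often profiled on platforms whose gene universe differs
#' from the reference cohort's, so the gene sets that survive ssGSEA can
#' differ too. Before prediction, both sides are restricted to the shared
#' gene-set names (term namespace), in reference order, and by default the
#' reference rank matrix is re-ranked over the surviving sets -- ranks are
#' only meaningful within a fixed gene-set universe, so stale full-space
#' ranks are not merely subsetted (set `rerank = FALSE` to keep them).
#'
#' @param test_es Genesets-by-samples enrichment matrix for the test data.
#' @param ref An `mb_reference`.
#' @param min_overlap Warn when fewer shared gene sets remain (default 10).
#' @param rerank Re-rank the reference over the shared sets (default TRUE).
#' @return A list with `geneset_names` (the intersection, reference order),
#'   `test_es` (restricted test matrix) and `ref_rank_matrix` (reference
#'   rank matrix over the shared sets).
#' @export
harmonize_genesets <- function(test_es, ref, min_overlap = 10, rerank = TRUE) {
  stopifnot(is.matrix(test_es), inherits(ref, "mb_reference"))
  shared <- intersect(ref$geneset_names, rownames(test_es))
  if (length(shared) == 0) {
    rlang::abort("no gene sets shared between test data and reference")
  }
  if (length(shared) < min_overlap) {
    rlang::warn(sprintf(
      "only %d gene set(s) shared between test data and reference (floor %d); predictions may be unstable",
      length(shared), min_overlap
    ))
  }
  ref_ranks <- ref$rank_matrix[, shared, drop = FALSE]
  if (rerank && length(shared) < length(ref$geneset_names)) {
    ref_ranks <- t(apply(ref_ranks, 1, rank, ties.method = "average"))
    colnames(ref_ranks) <- shared
  }
  list(
    geneset_names = shared,
    test_es = test_es[shared, , drop = FALSE],
    ref_rank_matrix = ref_ranks
  )
}

#' k-nearest-neighbour subtype vote for one rank vector
#'
#' Computes distances from a test sample's gene-set rank vector to every
#' reference sample's rank vector, takes the k nearest, and lets each
#' neighbour cast one vote for its subtype. The winning vote fraction is the
#' prediction confidence; at least 80% of votes makes a `high_confidence`
#' call, anything lower is `intermediate` (a sample between subtypes or
#' heterogeneous). All tie-breaks are deterministic: equal distances at the
#' k-th position are resolved by reference sample id (lexicographic), vote
#' ties by the smaller mean neighbour distance, then by canonical label
#' order ([mb_subtypes()]).
#'
#' @param test_rank_vector Named numeric vector of gene-set ranks, names
#'   matching `ref_rank_matrix` columns.
#' @param ref An `mb_reference`, or the harmonized list from
#'   [harmonize_genesets()] plus `labels`/`metric` arguments via `...` --
#'   normally called through [classify_human()]/[classify_mouse()].
#' @param k Number of neighbours (default: the reference's `k`).
#' @return A one-row tibble: `sample_id`, `predicted_subtype`,
#'   `confidence_percent`, `vote_<subtype>` counts, `call_class`, and a
#'   `neighbors` list-column of (ref_sample_id, subtype, distance).
#' @export
knn_predict <- function(test_rank_vector, ref, k = NULL) {
  stopifnot(inherits(ref, "mb_reference"))
  knn_vote(
    test_rank_vector, ref$rank_matrix, ref$labels,
    k = k %||% ref$hyperparams$k, metric = ref$hyperparams$metric,
    sample_id = names(test_rank_vector)[1] %||% "sample"
  )
}

knn_vote <- function(test_rank_vector, ref_rank_matrix, ref_labels, k,
                     metric = "euclidean", sample_id = "sample") {
  if (length(test_rank_vector) != ncol(ref_rank_matrix)) {
    rlang::abort(sprintf(
      "rank vector length %d does not match the %d reference gene sets",
      length(test_rank_vector), ncol(ref_rank_matrix)
    ))
  }
  if (k > nrow(ref_rank_matrix)) {
    rlang::abort(sprintf(
      "k = %d exceeds the %d reference samples", k, nrow(ref_rank_matrix)
    ))
  }
  if (!is.null(names(test_rank_vector)) &&
      all(colnames(ref_rank_matrix) %in% names(test_rank_vector))) {
    test_rank_vector <- test_rank_vector[colnames(ref_rank_matrix)]
  }
  diff <- sweep(ref_rank_matrix, 2, as.numeric(test_rank_vector))
  d <- switch(metric,
    euclidean = sqrt(rowSums(diff^2)),
    manhattan = rowSums(abs(diff)),
    rlang::abort(sprintf("unknown distance metric '%s'", metric))
  )
  ord <- order(d, rownames(ref_rank_matrix))
  nn <- ord[seq_len(k)]
  neighbors <- tibble::tibble(
    ref_sample_id = rownames(ref_rank_matrix)[nn],
    subtype = factor(as.character(ref_labels[nn]), levels = mb_subtypes()),
    distance = unname(d[nn])
  )
  votes <- table(neighbors$subtype)
  top <- max(votes)
  tied <- names(votes)[votes == top]
  if (length(tied) > 1) {
    mean_d <- vapply(tied, function(lb)
      mean(neighbors$distance[as.character(neighbors$subtype) == lb]), 0)
    tied <- tied[order(mean_d, match(tied, mb_subtypes()))]
  }
  predicted <- tied[1]
  confidence <- 100 * top / k
  out <- tibble::tibble(
    sample_id = sample_id,
    predicted_subtype = factor(predicted, levels = mb_subtypes()),
    confidence_percent = confidence,
    call_class = ifelse(confidence >= 80, "high_confidence", "intermediate"),
    neighbors = list(neighbors)
  )
  for (lb in mb_subtypes()) out[[paste0("vote_", lb)]] <- as.integer(votes[[lb]])
  out[, c("sample_id", "predicted_subtype", "confidence_percent",
          paste0("vote_", mb_subtypes()), "call_class", "neighbors")]
}

classify_core <- function(expr, ref, collection, k = NULL, min_overlap = 10,
                          rerank = TRUE) {
  stopifnot(inherits(ref, "mb_reference"))
  h <- ref$hyperparams
  k <- k %||% h$k
  es <- ssgsea(expr, collection, alpha = h$alpha, es_mode = h$es_mode)
  harm <- harmonize_genesets(es, ref, min_overlap = min_overlap,
                             rerank = rerank)
  test_ranks <- rank_transform(harm$test_es, harm$geneset_names)
  res <- purrr::map(colnames(expr), function(s) {
    knn_vote(test_ranks[s, ], harm$ref_rank_matrix, ref$labels,
             k = k, metric = h$metric, sample_id = s)
  })
  out <- dplyr::bind_rows(res)
  attr(out, "geneset_overlap") <- length(harm$geneset_names)
  attr(out, "hyperparams") <- utils::modifyList(h, list(k = as.integer(k)))
  class(out) <- c("mb_predictions", class(out))
  out
}

#' Classify human samples against the reference
#'
#' Runs the full single-sample pipeline for each column of a human
#' expression matrix: ssGSEA over the human gene-set collection,
#' harmonization to the gene sets shared with the reference, per-sample
#' descending-ES rank transform, and k-nearest-neighbour voting. Every
#' sample is classified independently -- adding or removing other samples
#' from the batch never changes a sample's prediction, and no reference
#' cerebellum sample or replicates are needed.
#'
#' @param expr Numeric genes-by-samples matrix of normalized human
#'   expression (any monotone-consistent per-sample scale).
#' @param ref An `mb_reference` from [build_reference()] or
#'   [load_reference()].
#' @param collection Human [gene_set_collection()] (same term namespace the
#'   reference was trained on).
#' @param k Override the reference's neighbour count.
#' @param min_overlap Shared-gene-set floor below which a warning is raised.
#' @param rerank Re-rank the reference after harmonization (default TRUE).
#' @return A tibble of class `mb_predictions`, one row per sample, with the
#'   columns described in [knn_predict()]; attributes record the gene-set
#'   overlap and hyperparameters used.
#' @export
#' @examples
#' sim <- simulate_cohort(simulation_config(n_per_class = 6, seed = 1))
#' ref <- build_reference(sim$expression, sim$labels, sim$gene_sets,
#'                        n_top = 25)
#' test <- simulate_cohort(simulation_config(n_per_class = 1, seed = 2))
#' classify_human(test$expression, ref, sim$gene_sets)
classify_human <- function(expr, ref, collection, k = NULL, min_overlap = 10,
                           rerank = TRUE) {
  if (gene_set_species(collection) != "human") {
    rlang::abort("classify_human() needs a human gene-set collection")
  }
  classify_core(expr, ref, collection, k = k, min_overlap = min_overlap,
                rerank = rerank)
}

#' Classify mouse samples against the (human-trained) reference
#'
#' Identical pipeline to [classify_human()] but scored with the mouse
#' gene-set collection, whose member genes are mouse symbols. The
#' cross-species bridge is the shared Gene Ontology Biological Process term
#' namespace: harmonization matches term names only, and no gene-level
#' ortholog translation happens at predict time.
#'
#' @inheritParams classify_human
#' @param collection Mouse [gene_set_collection()] sharing the reference's
#'   term namespace.
#' @return A tibble of class `mb_predictions` (see [classify_human()]).
#' @export
classify_mouse <- function(expr, ref, collection, k = NULL, min_overlap = 10,
                           rerank = TRUE) {
  if (gene_set_species(collection) != "mouse") {
    rlang::abort("classify_mouse() needs a mouse gene-set collection")
  }
  classify_core(expr, ref, collection, k = k, min_overlap = min_overlap,
                rerank = rerank)
}

#' Sample-centric prediction summary
#'
#' One row per sample with its call and per-subtype vote percentages --
#' the table behind the prediction heatmap and barplot.
#'
#' @param results An `mb_predictions` tibble.
#' @return A tibble: `sample_id`, `predicted_subtype`, `confidence_percent`,
#'   `call_class`, and `pct_<subtype>` vote percentages summing to 100.
#' @export
summarize_by_sample <- function(results) {
  if (!is.data.frame(results) || nrow(results) == 0) {
    rlang::abort("no prediction results to summarize")
  }
  k <- rowSums(as.matrix(results[, paste0("vote_", mb_subtypes())]))
  out <- results[, c("sample_id", "predicted_subtype", "confidence_percent",
                     "call_class")]
  for (lb in mb_subtypes()) {
    out[[paste0("pct_", lb)]] <- 100 * results[[paste0("vote_", lb)]] / k
  }
  tibble::as_tibble(out)
}

#' Subtype-centric prediction summary
#'
#' Aggregates a batch of predictions (typically sample replicates) by
#' predicted subtype: how many samples call each subtype, the fraction of
#' the batch (the pie-chart wedge), and the distribution of confidences of
#' the samples calling it -- the view that reveals the majority subtype and
#' the consensus strength across replicates.
#'
#' @param results An `mb_predictions` tibble.
#' @return A tibble with one row per subtype in [mb_subtypes()]:
#'   `subtype`, `n_samples`, `fraction`, `n_high_confidence`,
#'   `median_confidence`, and a `confidences` list-column holding exactly
#'   the confidence values of the samples predicted as that subtype.
#' @export
summarize_by_subtype <- function(results) {
  if (!is.data.frame(results) || nrow(results) == 0) {
    rlang::abort("no prediction results to summarize")
  }
  n <- nrow(results)
  purrr::map_dfr(mb_subtypes(), function(lb) {
    conf <- results$confidence_percent[results$predicted_subtype == lb]
    tibble::tibble(
      subtype = factor(lb, levels = mb_subtypes()),
      n_samples = length(conf),
      fraction = length(conf) / n,
      n_high_confidence = sum(conf >= 80),
      median_confidence = ifelse(length(conf) > 0, stats::median(conf), NA_real_),
      confidences = list(conf)
    )
  })
}
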