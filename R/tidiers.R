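#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a training reference
#'
#' One row per reference sample: its subtype label and its gene-set rank
#' vector as a list-column.
#'
#' @param x An `mb_reference`.
#' @param ... Ignored.
#' @return A tibble: `sample_id`, `subtype`, `ranks` (named numeric
#'   list-column over the reference gene sets).
#' @export
tidy.mb_reference <- function(x, ...) {
  tibble::tibble(
    sample_id = rownames(x$rank_matrix),
    subtype = factor(as.character(x$labels), levels = mb_subtypes()),
    ranks = purrr::map(seq_len(nrow(x$rank_matrix)),
                       ~ x$rank_matrix[.x, ])
  )
}

#' One-row summary of a training reference
#'
#' @param x An `mb_reference`.
#' @param ... Ignored.
#' @return A one-row tibble: sample and gene-set counts, class count and
#'   the stored hyperparameters.
#' @export
glance.mb_reference <- function(x, ...) {
  h <- x$hyperparams
  tibble::tibble(
    n_samples = nrow(x$rank_matrix),
    n_genesets = length(x$geneset_names),
    n_classes = length(unique(x$labels)),
    k = h$k, alpha = h$alpha, n_top = h$n_top,
    es_mode = h$es_mode, metric = h$metric,
    selection_statistic = h$selection_statistic
  )
}

#' One-row summary of a batch of predictions
#'
#' @param x An `mb_predictions` tibble.
#' @param ... Ignored.
#' @return A one-row tibble: batch size, majority subtype and its fraction,
#'   high-confidence fraction and mean confidence.
#' @export
glance.mb_predictions <- function(x, ...) {
  tab <- summarize_by_subtype(x)
  top <- tab[which.max(tab$n_samples), ]
  tibble::tibble(
    n_samples = nrow(x),
    majority_subtype = as.character(top$subtype),
    majority_fraction = top$fraction,
    high_confidence_fraction = mean(x$confidence_percent >= 80),
    mean_confidence = mean(x$confidence_percent)
  )
}
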