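#' Data behind the prediction heatmap
#'
#' Long-format vote percentages, one row per (sample, subtype): the
#' machine-readable twin of [plot_predictions_heatmap()], so plot content
#' can be checked numerically.
#'
#' @param results An `mb_predictions` tibble.
#' @return A tibble: `sample_id`, `subtype`, `vote_percent`.
#' @export
prediction_vote_data <- function(results) {
  if (!is.data.frame(results) || nrow(results) == 0) {
    rlang::abort("no prediction results to plot")
  }
  summarize_by_sample(results) |>
    tidyr::pivot_longer(
      dplyr::starts_with("pct_"),
      names_to = "subtype", names_prefix = "pct_", values_to = "vote_percent"
    ) |>
    dplyr::mutate(subtype = factor(.data$subtype, levels = mb_subtypes())) |>
    dplyr::select("sample_id", "subtype", "vote_percent")
}

#' Heatmap of vote percentages per sample and subtype
#'
#' Samples-by-subtypes grid of vote percentages; darker fill means higher
#' confidence that the sample belongs to that subtype.
#'
#' @param results An `mb_predictions` tibble.
#' @return A ggplot object.
#' @export
plot_predictions_heatmap <- function(results) {
  prediction_vote_data(results) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$subtype, y = .data$sample_id,
                                 fill = .data$vote_percent)) +
    ggplot2::geom_tile(colour = "grey85") +
    ggplot2::scale_fill_gradient(low = "white", high = "darkblue",
                                 limits = c(0, 100),
                                 name = "votes (%)") +
    ggplot2::labs(x = "subtype", y = "sample") +
    ggplot2::theme_minimal()
}

#' Stacked barplot of vote composition per sample
#'
#' @param results An `mb_predictions` tibble.
#' @return A ggplot object.
#' @export
plot_predictions_barplot <- function(results) {
  prediction_vote_data(results) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$sample_id, y = .data$vote_percent,
                                 fill = .data$subtype)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "sample", y = "votes (%)", fill = "subtype") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Pie chart of predicted-subtype fractions across a batch
#'
#' Wedge fractions equal `fraction` from [summarize_by_subtype()].
#'
#' @param summary Output of [summarize_by_subtype()], or an
#'   `mb_predictions` tibble (summarized internally).
#' @return A ggplot object.
#' @export
plot_subtype_pie <- function(summary) {
  if (!"fraction" %in% colnames(summary)) summary <- summarize_by_subtype(summary)
  dplyr::filter(summary, .data$n_samples > 0) |>
    ggplot2::ggplot(ggplot2::aes(x = "", y = .data$fraction,
                                 fill = .data$subtype)) +
    ggplot2::geom_col(width = 1, colour = "white") +
    ggplot2::coord_polar(theta = "y") +
    ggplot2::labs(fill = "predicted subtype", x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Boxplot of prediction confidences per predicted subtype
#'
#' Shows the overall strength of subtype calls across a batch: one box per
#' subtype over exactly the confidences of the samples predicted as it.
#'
#' @param summary Output of [summarize_by_subtype()], or an
#'   `mb_predictions` tibble.
#' @return A ggplot object.
#' @export
plot_confidence_boxplot <- function(summary) {
  if (!"confidences" %in% colnames(summary)) summary <- summarize_by_subtype(summary)
  summary |>
    dplyr::select("subtype", "confidences") |>
    tidyr::unnest("confidences") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$subtype, y = .data$confidences,
                                 fill = .data$subtype)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = "predicted subtype", y = "confidence (%)") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Project samples into the reference's principal-component space
#'
#' Fits a centred (unscaled) PCA on the reference rank matrix and projects
#' test rank vectors into the same space. Visualization only: subtype calls
#' always come from KNN voting in the full rank space, never from the
#' low-dimensional projection.
#'
#' @param ref An `mb_reference`.
#' @param test_rank_matrix Optional samples-by-genesets matrix of test rank
#'   vectors over the reference's gene sets.
#' @param n_comp Number of components to keep (default 3).
#' @return A list: `reference` (tibble of reference scores with `subtype`),
#'   `test` (tibble of test scores, or NULL), `var_explained` (fraction per
#'   kept component).
#' @export
pca_project <- function(ref, test_rank_matrix = NULL, n_comp = 3) {
  stopifnot(inherits(ref, "mb_reference"))
  n_comp <- min(n_comp, ncol(ref$rank_matrix), nrow(ref$rank_matrix) - 1)
  fit <- stats::prcomp(ref$rank_matrix, center = TRUE, scale. = FALSE)
  scores <- fit$x[, seq_len(n_comp), drop = FALSE]
  ref_tbl <- tibble::as_tibble(scores, rownames = "sample_id") |>
    dplyr::mutate(subtype = factor(as.character(ref$labels[.data$sample_id]),
                                   levels = mb_subtypes()))
  test_tbl <- NULL
  if (!is.null(test_rank_matrix)) {
    if (!identical(colnames(test_rank_matrix), colnames(ref$rank_matrix))) {
      test_rank_matrix <- test_rank_matrix[, colnames(ref$rank_matrix),
                                           drop = FALSE]
    }
    proj <- scale(test_rank_matrix, center = fit$center, scale = FALSE) %*%
      fit$rotation[, seq_len(n_comp), drop = FALSE]
    test_tbl <- tibble::as_tibble(proj, rownames = "sample_id")
  }
  list(
    reference = ref_tbl,
    test = test_tbl,
    var_explained = (fit$sdev^2 / sum(fit$sdev^2))[seq_len(n_comp)]
  )
}

#' PCA plot of test samples against the reference cohort
#'
#' Reference samples are coloured by subtype; test samples are overlaid in
#' purple. The caption reports the variance explained by the kept
#' components.
#'
#' @inheritParams pca_project
#' @param components Which two components to draw (default 1 and 2).
#' @return A ggplot object.
#' @export
plot_pca <- function(ref, test_rank_matrix = NULL, components = c(1, 2),
                     n_comp = 3) {
  proj <- pca_project(ref, test_rank_matrix, n_comp = max(n_comp, components))
  axes <- paste0("PC", components)
  cap <- paste0(
    "variance explained: ",
    paste(sprintf("PC%d %.1f%%", seq_along(proj$var_explained),
                  100 * proj$var_explained), collapse = ", ")
  )
  p <- ggplot2::ggplot(proj$reference,
                       ggplot2::aes(x = .data[[axes[1]]], y = .data[[axes[2]]],
                                    colour = .data$subtype)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(caption = cap) +
    ggplot2::theme_minimal()
  if (!is.null(proj$test)) {
    p <- p + ggplot2::geom_point(
      data = proj$test, colour = "purple", shape = 17, size = 3,
      mapping = ggplot2::aes(x = .data[[axes[1]]], y = .data[[axes[2]]]),
      inherit.aes = FALSE
    )
  }
  p
}

#' @rdname plot_predictions_heatmap
#' @param object An `mb_predictions` tibble.
#' @param ... Ignored.
#' @export
autoplot.mb_predictions <- function(object, ...) {
  plot_predictions_heatmap(object)
}
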