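#' Medulloblastoma subtype vocabulary
#'
#' The closed set of class labels the classifier works with: the four
#' consensus molecular subtypes plus a Normal (non-tumour) class.
#'
#' @return Character vector of the five labels, in canonical order
#'   (`WNT`, `SHH`, `Group3`, `Group4`, `Normal`). The order doubles as the
#'   final deterministic tie-break in voting.
#' @export
#' @examples
#' mb_subtypes()
mb_subtypes <- function() {
  c("WNT", "SHH", "Group3", "Group4", "Normal")
}

as_subtype_factor <- function(x, what = "label") {
  x <- as.character(x)
  bad <- setdiff(unique(x), mb_subtypes())
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "invalid %s value(s): %s (must be one of %s)",
      what, paste(bad, collapse = ", "), paste(mb_subtypes(), collapse = ", ")
    ))
  }
  factor(x, levels = mb_subtypes())
}

# stable decreasing-expression order: ties resolved by input position
stable_desc_order <- function(x) {
  order(-x, seq_along(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
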