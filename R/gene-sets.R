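#' Construct a gene-set collection
#'
#' A gene-set collection is a tibble with one row per set and columns
#' `name`, `description`, and `genes` (a list-column of character vectors),
#' carrying the species (`"human"` or `"mouse"`) as an attribute. Set names
#' are the cross-species bridge: human and mouse collections derived from the
#' same Gene Ontology Biological Process terms share the term namespace while
#' their member genes are species-specific symbols.
#'
#' Member gene symbols are opaque, case-sensitive strings; no alias mapping
#' is attempted. Duplicate members within a set are dropped, keeping the
#' first occurrence.
#'
#' @param name Character vector of unique set names.
#' @param genes List of character vectors, the member genes of each set.
#' @param description Character vector of set descriptions (recycled if
#'   length 1). Defaults to `"na"`.
#' @param species `"human"` or `"mouse"`.
#' @return A tibble of class `gene_set_collection`.
#' @export
#' @examples
#' gene_set_collection(
#'   name = c("GOBP_A", "GOBP_B"),
#'   genes = list(c("TP53", "MYC"), c("GLI1", "GLI2", "SMO")),
#'   species = "human"
#' )
gene_set_collection <- function(name, genes, description = "na",
                                species = c("human", "mouse")) {
  species <- match.arg(species)
  name <- as.character(name)
  if (anyDuplicated(name)) {
    rlang::abort(sprintf(
      "duplicate gene-set name(s): %s",
      paste(unique(name[duplicated(name)]), collapse = ", ")
    ))
  }
  if (!is.list(genes) || length(genes) != length(name)) {
    rlang::abort("`genes` must be a list of character vectors, one per set name")
  }
  genes <- purrr::map(genes, function(g) {
    g <- as.character(g)
    g[!duplicated(g)]
  })
  if (any(lengths(genes) == 0)) {
    rlang::abort("every gene set must have at least one member gene")
  }
  if (any(!nzchar(unlist(genes)))) {
    rlang::abort("empty gene symbols are not allowed")
  }
  description <- rep_len(as.character(description), length(name))
  out <- tibble::tibble(name = name, description = description, genes = genes)
  class(out) <- c("gene_set_collection", class(out))
  attr(out, "species") <- species
  out
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf(
    "<gene_set_collection> %d sets, species %s\n",
    nrow(x), attr(x, "species")
  ))
  NextMethod()
}

#' Species of a gene-set collection
#'
#' @param collection A [gene_set_collection()].
#' @return `"human"` or `"mouse"`.
#' @export
gene_set_species <- function(collection) {
  attr(collection, "species") %||% "human"
}

#' Read a GMT gene-set file
#'
#' Parses the Broad GMT convention: one set per line, tab-separated, UTF-8,
#' field 1 the set name, field 2 a description, fields 3+ the member genes.
#' Trailing empty fields are ignored; duplicate genes within a line are
#' deduplicated keeping the first occurrence. A line with fewer than three
#' non-empty fields, or a duplicated set name, is an error naming the line.
#'
#' @param path Path to a GMT file.
#' @param species `"human"` or `"mouse"`; recorded on the collection.
#' @return A [gene_set_collection()].
#' @seealso [write_gmt()]
#' @export
read_gmt <- function(path, species = c("human", "mouse")) {
  species <- match.arg(species)
  if (!file.exists(path)) {
    rlang::abort(sprintf("GMT file not found: %s", path))
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    rlang::abort(sprintf("GMT file is empty: %s", path))
  }
  parsed <- purrr::imap(lines, function(line, i) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    # trailing empty fields (e.g. editor-added tabs) are not genes
    while (length(fields) > 0 && !nzchar(fields[length(fields)])) {
      fields <- fields[-length(fields)]
    }
    if (length(fields) < 3) {
      rlang::abort(sprintf(
        "malformed GMT line %d in %s: expected at least 3 tab-separated fields, got %d",
        i, path, length(fields)
      ))
    }
    list(name = fields[1], description = fields[2], genes = fields[-(1:2)])
  })
  nm <- purrr::map_chr(parsed, "name")
  if (anyDuplicated(nm)) {
    dup <- unique(nm[duplicated(nm)])
    rlang::abort(sprintf(
      "duplicate gene-set name(s) in %s: %s", path, paste(dup, collapse = ", ")
    ))
  }
  gene_set_collection(
    name = nm,
    description = purrr::map_chr(parsed, "description"),
    genes = purrr::map(parsed, "genes"),
    species = species
  )
}

#' Write a gene-set collection to a GMT file
#'
#' Inverse of [read_gmt()]: `read_gmt(write_gmt(x, path), species)` returns
#' a collection identical to `x`.
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (any(lengths(collection$genes) == 0)) {
    rlang::abort("refusing to write a gene set with no member genes")
  }
  lines <- purrr::pmap_chr(
    list(collection$name, collection$description, collection$genes),
    function(n, d, g) paste(c(n, d, g), collapse = "\t")
  )
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
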