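#' Configuration for the synthetic cohort generator
#'
#' Describes a synthetic multi-subtype expression cohort: genes are
#' partitioned into disjoint gene-set blocks, each class owns a disjoint
#' block of signature gene sets, and a sample of class c is i.i.d. Gaussian
#' noise (a log-like scale, where Gaussian noise makes exact ties almost
#' surely absent) plus an upward mean shift of `signal_shift` noise-SD units
#' on c's signature genes. `mixing` blends a second class's signature into
#' each sample (`signal_shift * (1 - mixing)` on the own signature,
#' `signal_shift * mixing` on the partner's) to emulate intermediate
#' genotypes that should fall below the 80% confidence threshold.
#'
#' Defaults (30 samples per class, 1000 genes, 50 gene sets of 20 genes,
#' 3 signature sets per class, shift 3, noise SD 1, mixing 0) give a
#' strongly separated cohort at desk scale.
#'
#' @param n_per_class Samples simulated per class.
#' @param classes Character vector of class labels (subset of
#'   [mb_subtypes()]).
#' @param n_genes Total genes; must be at least `n_genesets * genes_per_set`.
#' @param n_genesets Total gene sets (disjoint blocks of genes).
#' @param genes_per_set Genes per gene set.
#' @param sets_per_class Signature gene sets owned by each class;
#'   `length(classes) * sets_per_class` must not exceed `n_genesets`.
#' @param signal_shift Mean shift (in noise-SD units) on signature genes.
#' @param noise_sd Standard deviation of the Gaussian background.
#' @param mixing In \[0, 1\]: 0 = pure subtypes, > 0 blends each class with
#'   the next class in `classes` (cyclic).
#' @param seed Integer seed; generation is fully reproducible from it (R's
#'   default Mersenne-Twister generator).
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_per_class = 30, classes = mb_subtypes(),
                              n_genes = 1000, n_genesets = 50,
                              genes_per_set = 20, sets_per_class = 3,
                              signal_shift = 3, noise_sd = 1, mixing = 0,
                              seed = 1) {
  classes <- as.character(classes)
  as_subtype_factor(classes, what = "class")
  if (anyDuplicated(classes)) rlang::abort("classes must be distinct")
  counts <- c(n_per_class = n_per_class, n_genes = n_genes,
              n_genesets = n_genesets, genes_per_set = genes_per_set,
              sets_per_class = sets_per_class)
  if (any(counts < 1) || any(counts != round(counts))) {
    rlang::abort("all counts must be positive integers")
  }
  if (n_genesets * genes_per_set > n_genes) {
    rlang::abort(sprintf(
      "n_genesets * genes_per_set = %d exceeds n_genes = %d",
      n_genesets * genes_per_set, n_genes
    ))
  }
  if (length(classes) * sets_per_class > n_genesets) {
    rlang::abort("not enough gene sets for disjoint per-class signatures")
  }
  if (mixing < 0 || mixing > 1) rlang::abort("mixing must be in [0, 1]")
  if (noise_sd <= 0) rlang::abort("noise_sd must be positive")
  structure(
    list(n_per_class = as.integer(n_per_class), classes = classes,
         n_genes = as.integer(n_genes), n_genesets = as.integer(n_genesets),
         genes_per_set = as.integer(genes_per_set),
         sets_per_class = as.integer(sets_per_class),
         signal_shift = signal_shift, noise_sd = noise_sd, mixing = mixing,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

sim_gene_ids <- function(config) sprintf("GENE%05d", seq_len(config$n_genes))

# deterministic layout shared by all generator functions: which genes each
# gene set contains and which gene sets are each class's signature
sim_layout <- function(config) {
  genes <- sim_gene_ids(config)
  set_genes <- purrr::map(seq_len(config$n_genesets), function(i) {
    genes[((i - 1) * config$genes_per_set + 1):(i * config$genes_per_set)]
  })
  n_sig <- length(config$classes) * config$sets_per_class
  set_names <- character(config$n_genesets)
  sig_sets <- list()
  for (j in seq_along(config$classes)) {
    idx <- ((j - 1) * config$sets_per_class + 1):(j * config$sets_per_class)
    set_names[idx] <- sprintf("GOBP_SIG_%s_%02d", toupper(config$classes[j]),
                              seq_along(idx))
    sig_sets[[config$classes[j]]] <- idx
  }
  if (n_sig < config$n_genesets) {
    set_names[(n_sig + 1):config$n_genesets] <-
      sprintf("GOBP_BACKGROUND_%03d", seq_len(config$n_genesets - n_sig))
  }
  list(genes = genes, set_genes = set_genes, set_names = set_names,
       signature_sets = sig_sets)
}

# mean-shift vector (length n_genes) for one class under the config's mixing
sim_class_template <- function(config, layout, class) {
  j <- match(class, config$classes)
  partner <- config$classes[(j %% length(config$classes)) + 1]
  mu <- numeric(config$n_genes)
  own_genes <- unlist(layout$set_genes[layout$signature_sets[[class]]])
  mu[match(own_genes, layout$genes)] <-
    config$signal_shift * (1 - config$mixing)
  if (config$mixing > 0 && partner != class) {
    partner_genes <- unlist(layout$set_genes[layout$signature_sets[[partner]]])
    mu[match(partner_genes, layout$genes)] <-
      mu[match(partner_genes, layout$genes)] + config$signal_shift * config$mixing
  }
  mu
}

#' Simulate a labelled multi-subtype expression cohort
#'
#' Generates `n_per_class` samples per class under the block-signature model
#' of [simulation_config()], together with the subtype labels and the
#' (human) gene-set collection describing the blocks. Output is bit-identical
#' across calls with the same config.
#'
#' @param config A [simulation_config()].
#' @return A list: `expression` (genes-by-samples matrix), `labels` (tibble
#'   `sample_id`, `subtype`) and `gene_sets` (a human
#'   [gene_set_collection()]).
#' @export
#' @examples
#' sim <- simulate_cohort(simulation_config(n_per_class = 2, seed = 7))
#' dim(sim$expression)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  layout <- sim_layout(config)
  classes <- config$classes
  sample_ids <- as.vector(t(outer(classes, seq_len(config$n_per_class),
                                  function(c, i) sprintf("%s_s%03d", c, i))))
  sample_class <- rep(classes, each = config$n_per_class)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  values <- matrix(
    stats::rnorm(config$n_genes * length(sample_ids), 0, config$noise_sd),
    nrow = config$n_genes,
    dimnames = list(layout$genes, sample_ids)
  )
  templates <- purrr::map(classes, ~ sim_class_template(config, layout, .x))
  names(templates) <- classes
  for (i in seq_along(sample_ids)) {
    values[, i] <- values[, i] + templates[[sample_class[i]]]
  }
  list(
    expression = values,
    labels = tibble::tibble(
      sample_id = sample_ids,
      subtype = factor(sample_class, levels = mb_subtypes())
    ),
    gene_sets = gene_set_collection(
      name = layout$set_names, genes = layout$set_genes,
      description = "synthetic gene-set block", species = "human"
    )
  )
}

#' Simulate a paired human/mouse gene-set collection
#'
#' Produces a mouse collection sharing the human collection's term names --
#' the cross-species bridge the classifier relies on -- with member genes
#' rewritten by the mouse symbol convention (first letter upper-case, rest
#' lower: `GENE00001` becomes `Gene00001`), plus the ortholog map recording
#' the transform. Optionally drops a fraction of terms from the mouse side
#' to emulate incomplete cross-species annotation.
#'
#' @param collection A human [gene_set_collection()].
#' @param drop_fraction Fraction of terms absent from the mouse collection
#'   (default 0 = every term shared).
#' @param seed Seed used only when `drop_fraction > 0`, to pick the dropped
#'   terms.
#' @return A list: `human` (the input collection), `mouse` (paired
#'   collection) and `ortholog_map` (tibble `mouse`, `human`).
#' @export
simulate_species_pair <- function(collection, drop_fraction = 0, seed = 1) {
  stopifnot(inherits(collection, "gene_set_collection"),
            drop_fraction >= 0, drop_fraction < 1)
  keep <- seq_len(nrow(collection))
  if (drop_fraction > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    n_drop <- floor(drop_fraction * nrow(collection))
    if (n_drop > 0) keep <- sort(sample(keep, nrow(collection) - n_drop))
  }
  human_genes <- sort(unique(unlist(collection$genes)))
  mouse_genes <- mouse_symbol(human_genes)
  mouse <- gene_set_collection(
    name = collection$name[keep],
    genes = purrr::map(collection$genes[keep], mouse_symbol),
    description = collection$description[keep],
    species = "mouse"
  )
  list(
    human = collection,
    mouse = mouse,
    ortholog_map = tibble::tibble(mouse = mouse_genes, human = human_genes)
  )
}

#' Mouse symbol convention used by the simulator
#'
#' @param x Character vector of human gene symbols.
#' @return The symbols rewritten first-letter-upper, rest lower.
#' @export
mouse_symbol <- function(x) {
  paste0(substr(x, 1, 1), tolower(substr(x, 2, nchar(x))))
}

#' Simulate replicate samples of one class template
#'
#' Draws `n_replicates` independent-noise samples from a single class's
#' signature template -- the situation of profiling many replicates of one
#' mouse model -- for exercising the subtype-centric summaries.
#'
#' @param config A [simulation_config()]; `mixing` and `signal_shift` act as
#'   in [simulate_cohort()].
#' @param n_replicates Number of replicate samples.
#' @param class The template class (must be in `config$classes`).
#' @return A genes-by-replicates expression matrix (columns `REP_001`, ...).
#' @export
simulate_replicates <- function(config, n_replicates, class) {
  stopifnot(inherits(config, "simulation_config"), n_replicates >= 1)
  if (!class %in% config$classes) {
    rlang::abort(sprintf("class '%s' is not in the config's classes", class))
  }
  layout <- sim_layout(config)
  mu <- sim_class_template(config, layout, class)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  values <- matrix(
    stats::rnorm(config$n_genes * n_replicates, 0, config$noise_sd),
    nrow = config$n_genes,
    dimnames = list(layout$genes, sprintf("REP_%03d", seq_len(n_replicates)))
  ) + mu
  values
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
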