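# Independent oracles and small fixture builders shared across test files.

# Naive per-position running-sum enrichment score. Walks the decreasing-
# expression gene order one position at a time with scalar accumulators --
# deliberately no cumsum/vectorized path shared with the implementation.
es_oracle <- function(x, gene_ids, set, alpha, es_mode = "integrated") {
  r <- rank(x, ties.method = "average")
  ord <- order(-x, seq_along(x))
  in_set <- gene_ids[ord] %in% set
  r_sorted <- unname(r[ord])
  G <- length(x)
  m <- sum(in_set)
  stopifnot(m > 0, m < G)
  denom_in <- sum(r_sorted[in_set]^alpha)
  sum_in <- 0
  n_out <- 0
  total <- 0
  best <- 0
  best_abs <- -1
  for (i in seq_len(G)) {
    if (in_set[i]) {
      sum_in <- sum_in + r_sorted[i]^alpha
    } else {
      n_out <- n_out + 1
    }
    d <- sum_in / denom_in - n_out / (G - m)
    total <- total + d
    if (abs(d) > best_abs) {
      best_abs <- abs(d)
      best <- d
    }
  }
  if (es_mode == "integrated") total else best
}

# Brute-force KNN: all pairwise distances computed element by element, full
# sort, independent re-derivation of the voting and tie-break rules.
knn_oracle <- function(test_vec, ref_matrix, ref_labels, k,
                       metric = "euclidean") {
  d <- numeric(nrow(ref_matrix))
  for (i in seq_len(nrow(ref_matrix))) {
    diff <- ref_matrix[i, ] - test_vec
    d[i] <- if (metric == "euclidean") sqrt(sum(diff^2)) else sum(abs(diff))
  }
  df <- data.frame(id = rownames(ref_matrix),
                   label = as.character(ref_labels),
                   d = d, stringsAsFactors = FALSE)
  df <- df[order(df$d, df$id), ]
  nn <- df[seq_len(k), ]
  votes <- sapply(mb_subtypes(), function(lb) sum(nn$label == lb))
  top_labels <- names(votes)[votes == max(votes)]
  if (length(top_labels) > 1) {
    md <- sapply(top_labels, function(lb) mean(nn$d[nn$label == lb]))
    top_labels <- top_labels[order(md, match(top_labels, mb_subtypes()))]
  }
  list(neighbor_ids = nn$id, votes = votes, predicted = top_labels[1],
       confidence = 100 * max(votes) / k)
}

# Random expression fixture with unique-ish values (Gaussian, ties a.s. absent)
random_expr <- function(n_genes, n_samples, prefix = "S") {
  matrix(rnorm(n_genes * n_samples),
         nrow = n_genes,
         dimnames = list(sprintf("G%04d", seq_len(n_genes)),
                         sprintf("%s%03d", prefix, seq_len(n_samples))))
}

# Random gene-set collection over a gene universe
random_collection <- function(n_sets, universe, min_size = 5, max_size = 30,
                              species = "human") {
  gene_set_collection(
    name = sprintf("GOBP_RND_%03d", seq_len(n_sets)),
    genes = lapply(seq_len(n_sets), function(i) {
      sample(universe, sample(min_size:max_size, 1))
    }),
    description = sprintf("random set %d", seq_len(n_sets)),
    species = species
  )
}

# Small trained reference on a simulated cohort (shared by several files)
small_reference <- function(n_per_class = 8, seed = 101, n_top = 25, k = 5) {
  sim <- simulate_cohort(simulation_config(n_per_class = n_per_class,
                                           seed = seed))
  ref <- build_reference(sim$expression, sim$labels, sim$gene_sets,
                         k = k, n_top = n_top)
  list(sim = sim, ref = ref)
}
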