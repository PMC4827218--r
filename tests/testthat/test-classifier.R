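test_that("harmonization restricts to shared gene sets and re-ranks the reference", {
  fix <- small_reference(n_per_class = 3, seed = 201, n_top = 20)
  ref <- fix$ref
  full_es <- matrix(rnorm(20 * 2), nrow = 20,
                    dimnames = list(ref$geneset_names, c("t1", "t2")))

  # full coverage: identity, reference ranks untouched
  h <- harmonize_genesets(full_es, ref)
  expect_equal(h$geneset_names, ref$geneset_names)
  expect_identical(h$ref_rank_matrix, ref$rank_matrix)

  # half coverage: reference rows re-ranked, closed-form row sums
  half <- ref$geneset_names[seq(1, 20, by = 2)]
  h2 <- harmonize_genesets(full_es[half, ], ref)
  expect_equal(h2$geneset_names, half)
  expect_equal(unname(rowSums(h2$ref_rank_matrix)),
               rep(10 * 11 / 2, nrow(ref$rank_matrix)))
  # re-rank oracle: rank of the subsetted ranks
  for (i in seq_len(nrow(ref$rank_matrix))) {
    expect_equal(h2$ref_rank_matrix[i, ],
                 rank(ref$rank_matrix[i, half], ties.method = "average"))
  }
  # opt-out keeps the stale subsetted ranks
  h3 <- harmonize_genesets(full_es[half, ], ref, rerank = FALSE)
  expect_identical(h3$ref_rank_matrix, ref$rank_matrix[, half])

  # disjoint namespaces
  rownames(full_es) <- paste0("OTHER_", seq_len(20))
  expect_error(harmonize_genesets(full_es, ref), "no gene sets shared")
  # low overlap warns
  es_small <- matrix(rnorm(3 * 1), nrow = 3,
                     dimnames = list(ref$geneset_names[1:3], "t1"))
  expect_warning(harmonize_genesets(es_small, ref), "only 3 gene set")
})

test_that("KNN voting matches a brute-force all-pairs oracle", {
  set.seed(303)
  n_gs <- 12
  for (n_ref in c(20, 80, 200)) {
    es <- matrix(rnorm(n_gs * n_ref), nrow = n_gs,
                 dimnames = list(sprintf("GS%02d", 1:n_gs),
                                 sprintf("r%03d", 1:n_ref)))
    rank_m <- rank_transform(es)
    labels <- factor(sample(mb_subtypes(), n_ref, replace = TRUE),
                     levels = mb_subtypes())
    names(labels) <- rownames(rank_m)
    ref <- mbsubtyper:::new_mb_reference(
      geneset_names = colnames(rank_m), rank_matrix = rank_m,
      labels = labels,
      hyperparams = list(alpha = 0.25, k = 5L, n_top = n_gs,
                         es_mode = "integrated", metric = "euclidean",
                         selection_statistic = "kruskal_wallis")
    )
    for (trial in 1:10) {
      test_vec <- rank(-rnorm(n_gs), ties.method = "average")
      names(test_vec) <- colnames(rank_m)
      got <- knn_predict(test_vec, ref)
      want <- knn_oracle(test_vec, rank_m, labels, k = 5)
      expect_equal(got$neighbors[[1]]$ref_sample_id, want$neighbor_ids)
      expect_equal(
        unname(unlist(got[paste0("vote_", mb_subtypes())])),
        unname(want$votes)
      )
      expect_equal(as.character(got$predicted_subtype), want$predicted)
      expect_equal(got$confidence_percent, want$confidence)
      # vote conservation and the confidence lattice for k = 5
      expect_equal(sum(unlist(got[paste0("vote_", mb_subtypes())])), 5)
      expect_true(got$confidence_percent %in% c(0, 20, 40, 60, 80, 100))
    }
  }
})

test_that("KNN tie-breaks are deterministic as specified", {
  gs <- c("A", "B")
  rank_m <- rbind(r1 = c(1, 2), r2 = c(2, 1), r3 = c(1, 2), r4 = c(2, 1))
  colnames(rank_m) <- gs
  labels <- factor(c("SHH", "Group3", "Group3", "SHH"), levels = mb_subtypes())
  names(labels) <- rownames(rank_m)
  ref <- mbsubtyper:::new_mb_reference(
    geneset_names = gs, rank_matrix = rank_m, labels = labels,
    hyperparams = list(alpha = 0.25, k = 2L, n_top = 2L,
                       es_mode = "integrated", metric = "euclidean",
                       selection_statistic = "kruskal_wallis")
  )
  # equidistant reference: k-th position ties resolved by sample id, so the
  # k = 2 neighbours are r1, r2 (lexicographic among four equal options
  # after the test vector sits in the middle)
  test_vec <- c(A = 1.5, B = 1.5)
  got <- knn_predict(test_vec, ref, k = 2)
  expect_equal(got$neighbors[[1]]$ref_sample_id, c("r1", "r2"))
  # 1-1 vote tie, equal mean distances -> canonical label order: SHH wins
  expect_equal(as.character(got$predicted_subtype), "SHH")
  expect_equal(got$call_class, "intermediate")

  # zero-distance exact match with k = 1 gives that label at confidence 100
  got1 <- knn_predict(c(A = 1, B = 2), ref, k = 1)
  expect_equal(got1$neighbors[[1]]$ref_sample_id, "r1")
  expect_equal(as.character(got1$predicted_subtype), "SHH")
  expect_equal(got1$confidence_percent, 100)
  expect_equal(got1$call_class, "high_confidence")

  expect_error(knn_predict(c(A = 1, B = 2), ref, k = 10),
               "exceeds the 4 reference samples")
  expect_error(knn_predict(c(A = 1, B = 2, C = 3), ref, k = 2),
               "does not match")
})

test_that("constructed 5/5, 4/5, 3/5 neighbour fixtures give 100/80/60 and the 80% rule", {
  gs <- sprintf("GS%d", 1:4)
  base <- c(1, 2, 3, 4)
  # reference samples placed at controlled distances from the origin profile
  rank_m <- rbind(
    a1 = base, a2 = base, a3 = base, a4 = base, a5 = base,
    b1 = c(4, 3, 2, 1), b2 = c(4, 3, 2, 1), b3 = c(4, 3, 2, 1)
  )
  colnames(rank_m) <- gs
  make_ref <- function(labels) {
    labels <- factor(labels, levels = mb_subtypes())
    names(labels) <- rownames(rank_m)
    mbsubtyper:::new_mb_reference(
      geneset_names = gs, rank_matrix = rank_m, labels = labels,
      hyperparams = list(alpha = 0.25, k = 5L, n_top = 4L,
                         es_mode = "integrated", metric = "euclidean",
                         selection_statistic = "kruskal_wallis")
    )
  }
  test_vec <- c(GS1 = 1, GS2 = 2, GS3 = 3, GS4 = 4)

  r5 <- knn_predict(test_vec, make_ref(
    c("Group3", "Group3", "Group3", "Group3", "Group3", "SHH", "SHH", "SHH")))
  expect_equal(r5$confidence_percent, 100)
  expect_equal(r5$call_class, "high_confidence")

  r4 <- knn_predict(test_vec, make_ref(
    c("Group3", "Group3", "Group3", "Group3", "SHH", "SHH", "SHH", "SHH")))
  expect_equal(as.character(r4$predicted_subtype), "Group3")
  expect_equal(r4$vote_Group3, 4L)
  expect_equal(r4$confidence_percent, 80)
  expect_equal(r4$call_class, "high_confidence")

  r3 <- knn_predict(test_vec, make_ref(
    c("Group3", "Group3", "Group3", "SHH", "WNT", "SHH", "SHH", "SHH")))
  expect_equal(r3$confidence_percent, 60)
  expect_equal(r3$call_class, "intermediate")
})

test_that("predictions are independent of batch composition", {
  fix <- small_reference(n_per_class = 5, seed = 401, n_top = 25)
  test <- simulate_cohort(simulation_config(n_per_class = 4, seed = 402))
  batch_all <- classify_human(test$expression, fix$ref, fix$sim$gene_sets)
  set.seed(403)
  for (trial in 1:8) {
    idx <- sample(ncol(test$expression), sample(1:10, 1))
    sub <- classify_human(test$expression[, idx, drop = FALSE], fix$ref,
                          fix$sim$gene_sets)
    for (s in colnames(test$expression)[idx]) {
      expect_equal(sub[sub$sample_id == s, ],
                   batch_all[batch_all$sample_id == s, ])
    }
  }
})

test_that("synthetic subtype templates are recovered by classification", {
  fix <- small_reference(n_per_class = 8, seed = 411, n_top = 15)
  test <- simulate_cohort(simulation_config(n_per_class = 3, seed = 412))
  res <- classify_human(test$expression, fix$ref, fix$sim$gene_sets)
  truth <- setNames(as.character(test$labels$subtype), test$labels$sample_id)
  expect_equal(as.character(res$predicted_subtype),
               unname(truth[res$sample_id]))
})

test_that("all-constant test samples are an explicit error", {
  fix <- small_reference(n_per_class = 3, seed = 421, n_top = 10)
  flat <- matrix(7, nrow = nrow(fix$sim$expression), ncol = 1,
                 dimnames = list(rownames(fix$sim$expression), "flat"))
  expect_error(classify_human(flat, fix$ref, fix$sim$gene_sets),
               "constant expression")
})

test_that("species guards reject mismatched collections", {
  fix <- small_reference(n_per_class = 3, seed = 431, n_top = 10)
  pair <- simulate_species_pair(fix$sim$gene_sets)
  expect_error(classify_human(fix$sim$expression, fix$ref, pair$mouse),
               "human gene-set collection")
  expect_error(classify_mouse(fix$sim$expression, fix$ref, fix$sim$gene_sets),
               "mouse gene-set collection")
})

test_that("mouse classification equals human classification on an ortholog-mapped fixture", {
  fix <- small_reference(n_per_class = 5, seed = 441, n_top = 25)
  pair <- simulate_species_pair(fix$sim$gene_sets)
  test <- simulate_cohort(simulation_config(n_per_class = 2, seed = 442))

  # translate the human fixture's gene ids to mouse symbols via the map
  to_mouse <- setNames(pair$ortholog_map$mouse, pair$ortholog_map$human)
  mouse_expr <- test$expression
  rownames(mouse_expr) <- unname(to_mouse[rownames(test$expression)])

  es_h <- ssgsea(test$expression, pair$human, alpha = 0.25)
  es_m <- ssgsea(mouse_expr, pair$mouse, alpha = 0.25)
  expect_identical(unname(es_m), unname(es_h))  # bit-identical ES

  res_h <- classify_human(test$expression, fix$ref, pair$human)
  res_m <- classify_mouse(mouse_expr, fix$ref, pair$mouse)
  expect_equal(res_m, res_h)
})

test_that("mouse GMTs with dropped terms harmonize to the constructed overlap", {
  fix <- small_reference(n_per_class = 4, seed = 451, n_top = 30)
  pair <- simulate_species_pair(fix$sim$gene_sets, drop_fraction = 0.3,
                                seed = 452)
  expect_equal(nrow(pair$mouse), 50 - floor(0.3 * 50))
  test <- simulate_cohort(simulation_config(n_per_class = 1, seed = 453))
  to_mouse <- setNames(pair$ortholog_map$mouse, pair$ortholog_map$human)
  mouse_expr <- test$expression
  rownames(mouse_expr) <- unname(to_mouse[rownames(test$expression)])
  res <- classify_mouse(mouse_expr, fix$ref, pair$mouse)
  expect_equal(attr(res, "geneset_overlap"),
               length(intersect(fix$ref$geneset_names, pair$mouse$name)))

  # zero term-name overlap is an error
  none <- pair$mouse
  none$name <- paste0("X_", none$name)
  expect_error(classify_mouse(mouse_expr, fix$ref, none),
               "no gene sets shared")
})

test_that("summaries tally predictions exactly", {
  fix <- small_reference(n_per_class = 5, seed = 461, n_top = 25)
  cfg <- simulation_config(n_per_class = 5, seed = 462)
  reps <- simulate_replicates(cfg, n_replicates = 20, class = "Group3")
  res <- classify_human(reps, fix$ref, fix$sim$gene_sets)

  by_sample <- summarize_by_sample(res)
  expect_equal(nrow(by_sample), 20)
  expect_equal(unname(rowSums(as.matrix(
    by_sample[, paste0("pct_", mb_subtypes())]))), rep(100, 20))

  by_subtype <- summarize_by_subtype(res)
  # naive tally oracle
  tally <- sapply(mb_subtypes(),
                  function(lb) sum(res$predicted_subtype == lb))
  expect_equal(by_subtype$n_samples, unname(tally))
  expect_equal(sum(by_subtype$n_samples), 20)
  expect_equal(by_subtype$fraction, unname(tally) / 20)
  for (i in seq_len(5)) {
    expect_equal(sort(by_subtype$confidences[[i]]),
                 sort(res$confidence_percent[
                   res$predicted_subtype == by_subtype$subtype[i]]))
  }
  expect_error(summarize_by_subtype(res[0, ]), "no prediction results")
  expect_error(summarize_by_sample(res[0, ]), "no prediction results")
})
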