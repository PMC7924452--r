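test_that("Jaccard similarity handles identity, disjointness and overlap", {
  expect_equal(jaccard_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(jaccard_similarity(c(1, 2), c(3, 4)), 0)
  expect_equal(jaccard_similarity(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_equal(jaccard_similarity(integer(0), integer(0)), 0)
})

test_that("normalised local alignment matches the affine-gap DP oracle", {
  expect_equal(normalized_local_alignment("MKTAYIAKQR", "MKTAYIAKQR"), 1)
  # no positive-scoring alignment
  expect_equal(normalized_local_alignment("PPPP", "GGGG"), 0)
  expect_error(normalized_local_alignment("", "AC"), "empty")

  sub <- blosum62()
  s1 <- "MKTAYIAKQRQI"
  s2 <- "MKTAYIAKQRQV"  # one substitution
  expected <- oracle_local_alignment_score(s1, s2, sub) /
    sqrt(oracle_local_alignment_score(s1, s1, sub) *
           oracle_local_alignment_score(s2, s2, sub))
  expect_equal(normalized_local_alignment(s1, s2), expected, tolerance = 1e-12)

  # randomized cases, including gapped optima
  set.seed(42)
  aa <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","V","Y")
  for (k in 1:8) {
    a <- paste(sample(aa, sample(8:16, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aa, sample(8:16, 1), replace = TRUE), collapse = "")
    ref <- oracle_local_alignment_score(a, b, sub)
    want <- if (ref <= 0) 0 else min(1, ref /
      sqrt(oracle_local_alignment_score(a, a, sub) *
             oracle_local_alignment_score(b, b, sub)))
    expect_equal(normalized_local_alignment(a, b), want, tolerance = 1e-12)
  }
})

test_that("information content matches the counting oracle and is monotone", {
  dag <- toy_dag()
  # 8 entities; terms c and f (descendants of a) annotate 2 of them
  ann <- list(e1 = "c", e2 = "f", e3 = "e", e4 = "e",
              e5 = "d", e6 = "e", e7 = "b", e8 = "d")
  ic <- information_content(dag, ann)
  expect_equal(ic[["r"]], 0)
  # term "a" covers entities annotated to c, f, d (a is parent of c and d)
  expect_equal(ic[["a"]], oracle_ic(dag, ann, "a"), tolerance = 1e-12)
  expect_equal(ic[["c"]], -log(2 / 8), tolerance = 1e-12)  # c covers e1, e2
  for (t in dag$terms) {
    expect_equal(ic[[t]], oracle_ic(dag, ann, t), tolerance = 1e-12)
  }
  # child never less informative than any parent
  for (i in seq_len(nrow(dag$edges))) {
    expect_gte(ic[[dag$edges$child[i]]], ic[[dag$edges$parent[i]]])
  }
  expect_error(information_content(dag, list(x = "zzz")), "outside the DAG")
})

test_that("semantic set similarity agrees with the exhaustive oracle", {
  dag <- toy_dag()
  ann <- list(e1 = "c", e2 = "f", e3 = "e", e4 = "e",
              e5 = "d", e6 = "e", e7 = "b", e8 = "d")
  ic <- information_content(dag, ann)
  # a singleton set at the max-IC term scores 1 against itself
  top <- dag$terms[which.max(unclass(ic)[dag$terms])]
  expect_equal(semantic_set_similarity(top, top, dag, ic), 1)
  # sets sharing only the root: IC(root) = 0
  # (c,f are under a; e only under b; common ancestor of f and e is r)
  expect_equal(semantic_set_similarity("f", "e", dag, ic), 0)
  # 3-term vs 2-term exhaustive comparison
  tA <- c("c", "d", "f"); tB <- c("e", "d")
  expect_equal(semantic_set_similarity(tA, tB, dag, ic),
               oracle_semantic_similarity(tA, tB, dag, ann),
               tolerance = 1e-12)
  expect_warning(v <- semantic_set_similarity(character(0), "c", dag, ic), "empty")
  expect_equal(v, 0)
})

test_that("network closeness follows exp(-b * shortest path)", {
  edges <- data.frame(a = c("p1", "p2", "p3", "p5"),
                      b = c("p2", "p3", "p4", "p6"),
                      stringsAsFactors = FALSE)
  expect_equal(ppi_closeness(edges, "p1", "p1"), 1)              # shared target
  expect_equal(ppi_closeness(edges, "p1", "p5"), 0)              # components
  d <- oracle_bfs_distance(edges, "p1", "p3")
  expect_equal(d, 2)
  expect_equal(ppi_closeness(edges, "p1", "p3"), exp(-2), tolerance = 1e-12)
  expect_equal(ppi_closeness(edges, "p1", "p3", decay = 0.5), exp(-1), tolerance = 1e-12)
  expect_warning(v <- ppi_closeness(edges, character(0), "p1"), "empty")
  expect_equal(v, 0)
  expect_error(ppi_closeness(edges, "p1", "p2", decay = 0), "positive")
  # set score is the max over target pairs
  expect_equal(ppi_closeness(edges, c("p1", "p5"), c("p4", "p6")), exp(-1),
               tolerance = 1e-12)
})

test_that("description cosine handles identity, orthogonality and overlap", {
  v1 <- c(t1 = 2, t2 = 1)
  expect_equal(description_cosine(v1, v1), 1)
  expect_equal(description_cosine(c(t1 = 1), c(t2 = 3)), 0)
  expect_equal(description_cosine(c(t1 = 1, t2 = 1), c(t1 = 1, t3 = 1)), 0.5)
  expect_equal(description_cosine(c(t1 = 0), c(t1 = 2)), 0)
})

test_that("the builder returns exactly 7 symmetric unit-diagonal matrices in [0,1]", {
  kb <- tiny_kb(seed = 13)
  mats <- build_similarity_matrices(kb)
  expect_named(mats, c(DRUG_MEASURES, DISEASE_MEASURES))
  for (m in names(mats)) {
    M <- unclass(mats[[m]])
    expect_true(isSymmetric(M), label = paste(m, "symmetric"))
    expect_true(all(M >= 0 & M <= 1), label = paste(m, "in [0,1]"))
    expect_true(all(diag(M) == 1), label = paste(m, "unit diagonal"))
  }
  expect_error(build_similarity_matrices(
    structure(list(drugs = list(), diseases = list(), proteins = list(),
                   ppi = kb$ppi[0, ], go_dag = kb$go_dag, hpo_dag = kb$hpo_dag,
                   vocab_size = 1, gold = kb$gold[0, ],
                   drug_cluster = integer(0), disease_cluster = integer(0),
                   protein_cluster = integer(0), gen_seed = 1,
                   gen_config = kb$gen_config), class = "knowledge_base")),
    "no drugs")
})

test_that("random matrix entries equal direct per-pair operation calls", {
  kb <- tiny_kb(seed = 17, n_drugs = 15, n_diseases = 10, n_proteins = 20,
                n_clusters = 3)
  mats <- build_similarity_matrices(kb)
  go_ic <- information_content(kb$go_dag, lapply(kb$proteins, `[[`, "go_terms"))
  hpo_ic <- information_content(kb$hpo_dag, lapply(kb$diseases, `[[`, "phenotype_terms"))
  set.seed(99)
  for (k in 1:20) {
    i <- sample(length(kb$drugs), 1); j <- sample(length(kb$drugs), 1)
    di <- kb$drugs[[i]]; dj <- kb$drugs[[j]]
    expect_equal(mats$chemical[i, j],
                 jaccard_similarity(di$fingerprint, dj$fingerprint),
                 tolerance = 1e-12)
    expect_equal(mats$side_effect[i, j],
                 jaccard_similarity(di$side_effects, dj$side_effects),
                 tolerance = 1e-12)
    if (i != j) {
      # drug-level target aggregation: max over target pairs
      seq_best <- max(outer(di$targets, dj$targets, Vectorize(function(p, q) {
        normalized_local_alignment(kb$proteins[[p]]$sequence,
                                   kb$proteins[[q]]$sequence)
      })))
      expect_equal(mats$target_seq[i, j], seq_best, tolerance = 1e-9)
      go_best <- max(outer(di$targets, dj$targets, Vectorize(function(p, q) {
        semantic_set_similarity(kb$proteins[[p]]$go_terms,
                                kb$proteins[[q]]$go_terms, kb$go_dag, go_ic)
      })))
      expect_equal(mats$go[i, j], go_best, tolerance = 1e-9)
      expect_equal(mats$ppi[i, j],
                   ppi_closeness(kb$ppi, di$targets, dj$targets),
                   tolerance = 1e-12)
    }
    a <- sample(length(kb$diseases), 1); b <- sample(length(kb$diseases), 1)
    expect_equal(mats$mesh[a, b],
                 description_cosine(kb$diseases[[a]]$description_vector,
                                    kb$diseases[[b]]$description_vector),
                 tolerance = 1e-12)
    if (a != b) {
      expect_equal(mats$hpo[a, b],
                   semantic_set_similarity(kb$diseases[[a]]$phenotype_terms,
                                           kb$diseases[[b]]$phenotype_terms,
                                           kb$hpo_dag, hpo_ic),
                   tolerance = 1e-9)
    }
  }
})

test_that("every measure separates clusters on a fully planted knowledge base", {
  kb <- generate_knowledge_base(generator_config(
    n_drugs = 30, n_diseases = 20, n_proteins = 40, n_clusters = 5,
    signal_strength = 1, modality_noise = 0,
    go_size = 60, hpo_size = 50, seq_length = 60, vocab_size = 100,
    n_side_effect_terms = 40, seed = 23))
  mats <- build_similarity_matrices(kb)
  off_d <- !diag(TRUE, length(kb$drugs))
  same_d <- outer(kb$drug_cluster, kb$drug_cluster, `==`) & off_d
  for (m in DRUG_MEASURES) {
    M <- unclass(mats[[m]])
    expect_gt(mean(M[same_d]), mean(M[off_d & !same_d]), label = m)
  }
  off_s <- !diag(TRUE, length(kb$diseases))
  same_s <- outer(kb$disease_cluster, kb$disease_cluster, `==`) & off_s
  for (m in DISEASE_MEASURES) {
    M <- unclass(mats[[m]])
    expect_gt(mean(M[same_s]), mean(M[off_s & !same_s]), label = m)
  }
})

test_that("similarity matrices round-trip through CSV", {
  kb <- tiny_kb(seed = 29, n_drugs = 8, n_diseases = 6, n_proteins = 10,
                n_clusters = 2)
  mats <- build_similarity_matrices(kb)
  path <- withr::local_tempfile(fileext = ".csv")
  write_similarity_matrix(mats$chemical, path)
  back <- read_similarity_matrix(path, "chemical")
  expect_equal(unclass(back), unclass(mats$chemical), tolerance = 1e-12)
  expect_identical(attr(back, "measure_id"), "chemical")
})
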