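mk_sim <- function(ids, fill = 0.5) {
  n <- length(ids)
  M <- matrix(fill, n, n, dimnames = list(ids, ids))
  diag(M) <- 1
  repurpose:::new_similarity_matrix(M, "toy")
}

test_that("fuse_pair reproduces hand-derived values", {
  ds <- mk_sim(c("d1", "d2")); ss <- mk_sim(c("s1", "s2"))
  ds["d1", "d2"] <- ds["d2", "d1"] <- 0.64
  ss["s1", "s2"] <- ss["s2", "s1"] <- 0.25

  # only evidence is the pair itself and exclude_self is on -> 0
  known_self <- data.frame(drug_id = "d1", disease_id = "s1")
  expect_equal(fuse_pair("d1", "s1", ds, ss, known_self,
                         fusion_config(exclude_self = TRUE)), 0)

  # single candidate: sqrt(0.64 * 0.25) = 0.4
  known <- data.frame(drug_id = "d2", disease_id = "s2")
  expect_equal(fuse_pair("d1", "s1", ds, ss, known), 0.4, tolerance = 1e-12)

  expect_error(fuse_pair("nope", "s1", ds, ss, known), "unknown drug")
})

test_that("fuse_pair agrees with enumeration for several candidates and both aggregations", {
  set.seed(31)
  dids <- paste0("d", 1:5); sids <- paste0("s", 1:4)
  ds <- mk_sim(dids); ss <- mk_sim(sids)
  ds[,] <- runif(25); ds[] <- (unclass(ds) + t(unclass(ds))) / 2; diag(ds) <- 1
  ss[,] <- runif(16); ss[] <- (unclass(ss) + t(unclass(ss))) / 2; diag(ss) <- 1
  known <- data.frame(drug_id = c("d2", "d3", "d4"),
                      disease_id = c("s2", "s1", "s3"))
  for (agg in c("max", "mean")) {
    for (w in c(0.3, 0.5, 0.7)) {
      cfg <- fusion_config(w = w, aggregation = agg)
      expect_equal(fuse_pair("d1", "s1", ds, ss, known, cfg),
                   oracle_fuse("d1", "s1", ds, ss, known, w, agg),
                   tolerance = 1e-12,
                   label = paste("agg", agg, "w", w))
    }
  }
})

test_that("the feature table has exactly the 10 ordered feature columns", {
  kb <- tiny_kb(seed = 37, n_drugs = 10, n_diseases = 8, n_proteins = 12,
                n_clusters = 2)
  mats <- build_similarity_matrices(kb)
  pairs <- data.frame(drug_id = names(kb$drugs)[1:4],
                      disease_id = names(kb$diseases)[1:4],
                      label = c(1L, 0L, 1L, 0L))
  ft <- build_feature_table(mats, pairs, kb$gold)
  want <- c("chemical_mesh", "chemical_hpo", "side_effect_mesh", "side_effect_hpo",
            "target_seq_mesh", "target_seq_hpo", "go_mesh", "go_hpo",
            "ppi_mesh", "ppi_hpo")
  expect_identical(setdiff(names(ft), c("drug_id", "disease_id", "label")), want)
  expect_true(all(as.matrix(ft[want]) >= 0 & as.matrix(ft[want]) <= 1))
  expect_error(build_feature_table(mats, rbind(pairs, pairs[1, ]), kb$gold),
               "duplicate")
})

test_that("all-zero similarity matrices produce all-zero features", {
  ids_d <- paste0("d", 1:3); ids_s <- paste0("s", 1:3)
  zero_d <- mk_sim(ids_d, 0); zero_s <- mk_sim(ids_s, 0)
  diag(zero_d) <- 0; diag(zero_s) <- 0
  mats <- list(chemical = zero_d, side_effect = zero_d, target_seq = zero_d,
               go = zero_d, ppi = zero_d, mesh = zero_s, hpo = zero_s)
  pairs <- data.frame(drug_id = "d1", disease_id = "s1")
  known <- data.frame(drug_id = c("d2", "d3"), disease_id = c("s2", "s3"))
  ft <- build_feature_table(mats, pairs, known)
  expect_true(all(ft[repurpose:::feature_column_names()] == 0))
})

test_that("a toy instance matches the cell-by-cell brute-force oracle", {
  kb <- tiny_kb(seed = 41, n_drugs = 4, n_diseases = 3, n_proteins = 8,
                n_clusters = 2)
  mats <- build_similarity_matrices(kb)
  pairs <- expand.grid(drug_id = names(kb$drugs), disease_id = names(kb$diseases),
                       stringsAsFactors = FALSE)
  known <- kb$gold
  for (agg in c("max", "mean")) {
    cfg <- fusion_config(aggregation = agg)
    ft <- build_feature_table(mats, pairs, known, cfg)
    for (r in seq_len(nrow(ft))) {
      for (dm in DRUG_MEASURES) for (sm in DISEASE_MEASURES) {
        expect_equal(
          ft[r, paste(dm, sm, sep = "_")],
          oracle_fuse(ft$drug_id[r], ft$disease_id[r], mats[[dm]], mats[[sm]],
                      known, 0.5, agg, exclude_self = TRUE),
          tolerance = 1e-12)
      }
    }
  }
})

test_that("fused values never exceed the best drug-side candidate similarity", {
  kb <- tiny_kb(seed = 43, n_drugs = 12, n_diseases = 8, n_proteins = 14,
                n_clusters = 3)
  mats <- build_similarity_matrices(kb)
  pairs <- expand.grid(drug_id = names(kb$drugs)[1:6],
                       disease_id = names(kb$diseases)[1:4],
                       stringsAsFactors = FALSE)
  ft <- build_feature_table(mats, pairs, kb$gold)
  for (dm in DRUG_MEASURES) {
    cap <- apply(unclass(mats[[dm]])[pairs$drug_id, kb$gold$drug_id, drop = FALSE], 1, max)
    for (sm in DISEASE_MEASURES) {
      expect_true(all(ft[[paste(dm, sm, sep = "_")]] <= cap + 1e-12))
    }
  }
})

test_that("increasing a candidate similarity never decreases a max-fused value", {
  ids_d <- paste0("d", 1:3); ids_s <- paste0("s", 1:3)
  ds <- mk_sim(ids_d, 0.4); ss <- mk_sim(ids_s, 0.6)
  known <- data.frame(drug_id = c("d2", "d3"), disease_id = c("s2", "s3"))
  base <- fuse_pair("d1", "s1", ds, ss, known)
  ds2 <- ds; ds2["d1", "d2"] <- ds2["d2", "d1"] <- 0.9
  expect_gte(fuse_pair("d1", "s1", ds2, ss, known), base)
})

test_that("the leakage guard removes a positive pair's own evidence", {
  ids_d <- paste0("d", 1:2); ids_s <- paste0("s", 1:2)
  ds <- mk_sim(ids_d, 0.1); ss <- mk_sim(ids_s, 0.1)
  known <- data.frame(drug_id = c("d1", "d2"), disease_id = c("s1", "s2"))
  pairs <- data.frame(drug_id = "d1", disease_id = "s1", label = 1L)
  ft_guard <- build_feature_table(mats <- list(
    chemical = ds, side_effect = ds, target_seq = ds, go = ds, ppi = ds,
    mesh = ss, hpo = ss), pairs, known, fusion_config(exclude_self = TRUE))
  ft_leak <- build_feature_table(mats, pairs, known, fusion_config(exclude_self = FALSE))
  # with leakage the pair sees itself at similarity 1 x 1 = 1
  expect_equal(ft_leak$chemical_mesh, 1)
  expect_equal(ft_guard$chemical_mesh, 0.1)
})

test_that("feature tables round-trip through CSV", {
  kb <- tiny_kb(seed = 47, n_drugs = 6, n_diseases = 4, n_proteins = 8,
                n_clusters = 2)
  mats <- build_similarity_matrices(kb)
  ft <- build_feature_table(mats, cbind(kb$gold[1:5, ], label = 1L), kb$gold)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ft, path)
  back <- read_feature_table(path)
  expect_equal(as.data.frame(back), as.data.frame(ft), tolerance = 1e-12)
})
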