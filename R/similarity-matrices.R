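new_similarity_matrix <- function(values, measure_id) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  structure(values, measure_id = measure_id, class = c("similarity_matrix", "matrix"))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("<similarity_matrix> measure '", attr(x, "measure_id"), "', ",
      nrow(x), " x ", ncol(x), " entities\n", sep = "")
  invisible(x)
}

#' Measure identifiers
#'
#' The five drug-drug measures and two disease-disease measures, in feature
#' order.
#' @name measure_ids
#' @export
DRUG_MEASURES <- c("chemical", "side_effect", "target_seq", "go", "ppi")

#' @rdname measure_ids
#' @export
DISEASE_MEASURES <- c("mesh", "hpo")

# Jaccard similarity matrix from a list of sets, via the binary incidence
# matrix: intersections = X X^T, unions = |a| + |b| - intersections.
jaccard_matrix <- function(sets, universe = NULL) {
  ids <- names(sets)
  universe <- universe %||% sort(unique(unlist(sets, use.names = FALSE)))
  if (!length(universe)) {
    return(matrix(0, length(ids), length(ids), dimnames = list(ids, ids)))
  }
  X <- matrix(0, length(ids), length(universe), dimnames = list(ids, NULL))
  uindex <- stats::setNames(seq_along(universe), universe)
  for (i in seq_along(sets)) {
    if (length(sets[[i]])) X[i, uindex[as.character(sets[[i]])]] <- 1
  }
  inter <- tcrossprod(X)
  sz <- rowSums(X)
  un <- outer(sz, sz, `+`) - inter
  S <- ifelse(un > 0, inter / un, 0)
  diag(S) <- 1  # diagonal stays 1 even for entities missing the modality
  dimnames(S) <- list(ids, ids)
  S
}

# normalized local alignment similarity over a set of sequences; one
# vectorised alignment call per subject sequence
alignment_matrix <- function(sequences, scoring) {
  ids <- names(sequences)
  n <- length(sequences)
  seqs <- Biostrings::AAStringSet(unlist(sequences))
  self <- vapply(seq_len(n), function(i) sw_score(seqs[i], seqs[[i]], scoring), 0)
  S <- diag(1, n)
  dimnames(S) <- list(ids, ids)
  for (j in seq_len(n - 1L)) {
    idx <- (j + 1L):n
    sc <- pmax(0, sw_score(seqs[idx], seqs[[j]], scoring))
    val <- clip01(sc / sqrt(self[idx] * self[j]))
    S[j, idx] <- val
    S[idx, j] <- val
  }
  S
}

# Best-match-average matrix over entities' term sets, given the term-level
# normalized MICA similarity matrix; deduplicates identical term sets.
# unit_diag = TRUE forces entity-vs-itself entries to 1 (the convention for
# a SimilarityMatrix); FALSE keeps the true semantic self-similarity of the
# term set (mean normalised IC), which is what target-pair aggregation over
# shared proteins must see.
bma_matrix <- function(term_sets, term_sim, unit_diag = TRUE) {
  ids <- names(term_sets)
  key <- vapply(term_sets, function(t) paste(sort(t), collapse = "|"), "")
  uniq <- !duplicated(key)
  rep_of <- match(key, key[uniq])
  usets <- term_sets[uniq]
  m <- length(usets)
  U <- diag(1, m)
  empty <- lengths(usets) == 0
  for (i in seq_len(m)) {
    if (empty[i]) { U[i, ] <- 0; U[, i] <- 0; next }
    ti <- usets[[i]]
    # j == i included: the semantic self-similarity of a term set is the
    # mean normalised IC of its terms, not 1 — it matters for distinct
    # entities that share a term set
    for (j in seq_len(i)) {
      sub <- term_sim[ti, usets[[j]], drop = FALSE]
      v <- (mean(apply(sub, 1, max)) + mean(apply(sub, 2, max))) / 2
      U[i, j] <- U[j, i] <- v
    }
  }
  S <- U[rep_of, rep_of, drop = FALSE]
  if (unit_diag) diag(S) <- 1
  dimnames(S) <- list(ids, ids)
  clip01_mat(S)
}

clip01_mat <- function(S) { S[S < 0] <- 0; S[S > 1] <- 1; S }

# aggregate a protein-level similarity matrix to drug level by the maximum
# over target pairs
aggregate_targets_max <- function(protein_sim, targets) {
  ids <- names(targets)
  n <- length(ids)
  S <- diag(1, n)
  dimnames(S) <- list(ids, ids)
  idx <- lapply(targets, function(t) match(t, rownames(protein_sim)))
  has <- lengths(targets) > 0
  for (i in seq_len(n)) {
    if (!has[i]) { S[i, ] <- 0; S[, i] <- 0; next }
    for (j in seq_len(i - 1L)) {
      if (!has[j]) next
      S[i, j] <- S[j, i] <- max(protein_sim[idx[[i]], idx[[j]]])
    }
  }
  diag(S) <- 1
  S
}

#' Compute the five drug-drug and two disease-disease similarity matrices
#'
#' Drug measures: `chemical` (Tanimoto on fingerprint bit-sets),
#' `side_effect` (Jaccard on side-effect term sets), `target_seq`
#' (normalised Smith-Waterman between target sequences), `go` (Resnik
#' best-match-average over target GO annotations), `ppi` (exponential-decay
#' network closeness of targets). Disease measures: `mesh` (cosine of
#' description vectors), `hpo` (Resnik best-match-average over phenotype
#' terms). Protein-level scores aggregate to drug level by the maximum over
#' target pairs. Entities missing a modality score 0 against everything in
#' that measure (diagonal kept at 1), with a warning.
#'
#' @param kb a `knowledge_base`.
#' @param scoring an [alignment_scoring()] for the sequence measure.
#' @param decay decay rate for the network-closeness measure.
#' @return named list of 7 `similarity_matrix` objects (`chemical`,
#'   `side_effect`, `target_seq`, `go`, `ppi`, `mesh`, `hpo`).
#' @export
build_similarity_matrices <- function(kb, scoring = alignment_scoring(), decay = 1) {
  validate_knowledge_base(kb)
  if (!length(kb$drugs) || !length(kb$diseases)) {
    stop_input("build_similarity_matrices: knowledge base has no drugs or no diseases")
  }
  drug_ids <- names(kb$drugs)
  disease_ids <- names(kb$diseases)

  fp <- lapply(kb$drugs, `[[`, "fingerprint")
  se <- lapply(kb$drugs, `[[`, "side_effects")
  targets <- lapply(kb$drugs, `[[`, "targets")
  if (any(lengths(targets) == 0)) {
    warning("drugs without targets: sequence/GO/PPI measures score 0 for them")
  }
  if (any(lengths(fp) == 0)) warning("drugs without fingerprints score 0 on 'chemical'")
  if (any(lengths(se) == 0)) warning("drugs without side effects score 0 on 'side_effect'")

  chem <- jaccard_matrix(fp, universe = 0:(max(unlist(fp), 0) + 1L))
  sidefx <- jaccard_matrix(se)

  seqs <- lapply(kb$proteins, `[[`, "sequence")
  prot_seq_sim <- alignment_matrix(seqs, scoring)
  tseq <- aggregate_targets_max(prot_seq_sim, targets)

  go_ann <- lapply(kb$proteins, `[[`, "go_terms")
  go_ic <- information_content(kb$go_dag, go_ann)
  go_term_sim <- mica_ic_matrix(kb$go_dag, go_ic)
  mx <- max(go_term_sim)
  if (mx > 0) go_term_sim <- go_term_sim / mx
  prot_go_sim <- bma_matrix(go_ann, go_term_sim, unit_diag = FALSE)
  go <- aggregate_targets_max(prot_go_sim, targets)

  gr <- igraph::graph_from_data_frame(kb$ppi, directed = FALSE,
                                      vertices = names(kb$proteins))
  d <- igraph::distances(gr)
  prot_ppi_sim <- exp(-decay * d)
  prot_ppi_sim[!is.finite(d)] <- 0
  diag(prot_ppi_sim) <- 1
  ppi <- aggregate_targets_max(prot_ppi_sim, targets)

  dv <- lapply(kb$diseases, `[[`, "description_vector")
  vocab <- sort(unique(unlist(lapply(dv, names))))
  V <- matrix(0, length(dv), length(vocab), dimnames = list(disease_ids, vocab))
  for (i in seq_along(dv)) V[i, names(dv[[i]])] <- as.numeric(dv[[i]])
  nrm <- sqrt(rowSums(V^2))
  Vn <- V / ifelse(nrm > 0, nrm, 1)
  mesh <- clip01_mat(tcrossprod(Vn))
  diag(mesh) <- 1
  dimnames(mesh) <- list(disease_ids, disease_ids)

  hpo_ann <- lapply(kb$diseases, `[[`, "phenotype_terms")
  hpo_ic <- information_content(kb$hpo_dag, hpo_ann)
  hpo_term_sim <- mica_ic_matrix(kb$hpo_dag, hpo_ic)
  mx <- max(hpo_term_sim)
  if (mx > 0) hpo_term_sim <- hpo_term_sim / mx
  hpo <- bma_matrix(hpo_ann, hpo_term_sim)

  out <- list(
    chemical = new_similarity_matrix(clip01_mat(chem), "chemical"),
    side_effect = new_similarity_matrix(clip01_mat(sidefx), "side_effect"),
    target_seq = new_similarity_matrix(clip01_mat(tseq), "target_seq"),
    go = new_similarity_matrix(clip01_mat(go), "go"),
    ppi = new_similarity_matrix(clip01_mat(ppi), "ppi"),
    mesh = new_similarity_matrix(mesh, "mesh"),
    hpo = new_similarity_matrix(hpo, "hpo")
  )
  for (m in DRUG_MEASURES) stopifnot(identical(rownames(out[[m]]), drug_ids))
  for (m in DISEASE_MEASURES) stopifnot(identical(rownames(out[[m]]), disease_ids))
  out
}

#' Write / read a similarity matrix as CSV
#'
#' CSV with a header row and a leading column of entity ids.
#'
#' @param m a `similarity_matrix`.
#' @param path CSV file path.
#' @return `path` invisibly for the writer; a `similarity_matrix` for the
#'   reader.
#' @export
write_similarity_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), as.data.frame(unclass(m), check.names = FALSE),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @param measure_id measure label to attach on read.
#' @rdname write_similarity_matrix
#' @export
read_similarity_matrix <- function(path, measure_id = NA_character_) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  new_similarity_matrix(m, measure_id)
}
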