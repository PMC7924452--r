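# Independent brute-force oracles used to verify the package's composite
# operations on small instances. These deliberately share no code with the
# implementation.

# affine-gap Smith-Waterman (Gotoh recurrences); a gap of length L costs
# open + extend * L
oracle_local_alignment_score <- function(s1, s2, sub, open = 10, extend = 0.5) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - extend, E[i, j - 1] - extend)
      F[i, j] <- max(H[i - 1, j] - open - extend, F[i - 1, j] - extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + sub[a[i - 1], b[j - 1]], E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}

# all ancestors of a term (including itself) by naive repeated edge walking
oracle_ancestors <- function(dag, term) {
  anc <- term
  repeat {
    parents <- dag$edges$parent[dag$edges$child %in% anc]
    new <- setdiff(parents, anc)
    if (!length(new)) break
    anc <- c(anc, new)
  }
  sort(anc)
}

# IC by direct counting: how many entities have >= 1 annotation whose
# ancestor set contains the term
oracle_ic <- function(dag, annotations, term) {
  covered <- vapply(annotations, function(terms) {
    any(vapply(terms, function(t) term %in% oracle_ancestors(dag, t), TRUE))
  }, TRUE)
  n_root <- sum(vapply(annotations, length, 0L) > 0)
  cnt <- sum(covered)
  if (cnt == 0) cnt <- 1
  max(0, -log(cnt / n_root))
}

# best-match-average semantic similarity by exhaustive ancestor enumeration
oracle_semantic_similarity <- function(tA, tB, dag, annotations) {
  ics <- vapply(dag$terms, function(t) oracle_ic(dag, annotations, t), 0)
  names(ics) <- dag$terms
  mx <- max(ics)
  if (mx == 0) return(0)
  pair <- function(t1, t2) {
    common <- intersect(oracle_ancestors(dag, t1), oracle_ancestors(dag, t2))
    max(ics[common]) / mx
  }
  M <- outer(tA, tB, Vectorize(pair))
  (mean(apply(M, 1, max)) + mean(apply(M, 2, max))) / 2
}

# unweighted shortest path by hand-rolled breadth-first search
oracle_bfs_distance <- function(edges, from, to) {
  if (from == to) return(0)
  adj <- list()
  for (i in seq_len(nrow(edges))) {
    adj[[edges$a[i]]] <- c(adj[[edges$a[i]]], edges$b[i])
    adj[[edges$b[i]]] <- c(adj[[edges$b[i]]], edges$a[i])
  }
  frontier <- from; seen <- from; d <- 0
  while (length(frontier)) {
    d <- d + 1
    frontier <- setdiff(unique(unlist(adj[frontier])), seen)
    if (to %in% frontier) return(d)
    seen <- c(seen, frontier)
  }
  Inf
}

# fused feature by direct enumeration over the known associations
oracle_fuse <- function(d, s, drug_sim, disease_sim, known, w = 0.5,
                        aggregation = "max", exclude_self = TRUE) {
  vals <- numeric(0)
  for (i in seq_len(nrow(known))) {
    dp <- known$drug_id[i]; sp <- known$disease_id[i]
    if (exclude_self && dp == d && sp == s) next
    vals <- c(vals, drug_sim[d, dp]^w * disease_sim[s, sp]^(1 - w))
  }
  if (!length(vals)) return(0)
  if (aggregation == "max") max(vals) else mean(vals)
}

# ROC AUC by exhaustive concordance counting over positive-negative pairs
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  conc <- 0
  for (p in pos) for (q in neg) {
    conc <- conc + (p > q) + 0.5 * (p == q)
  }
  conc / (length(pos) * length(neg))
}

# small knowledge base for fast tests
tiny_kb <- function(seed = 7, n_drugs = 24, n_diseases = 16, n_proteins = 30,
                    n_clusters = 4, rho = 0.9, noise = 0.05) {
  generate_knowledge_base(generator_config(
    n_drugs = n_drugs, n_diseases = n_diseases, n_proteins = n_proteins,
    n_clusters = n_clusters, signal_strength = rho, modality_noise = noise,
    go_size = 60, hpo_size = 50, seq_length = 60, vocab_size = 100,
    n_side_effect_terms = 40, seed = seed))
}

# hand-built 7-term DAG:      r
#                            / \
#                           a   b
#                          / \ / \
#                         c   d   e      (d has two parents: a and b)
#                         |
#                         f
toy_dag <- function() {
  dag <- list(
    terms = c("r", "a", "b", "c", "d", "e", "f"),
    root = "r",
    edges = data.frame(
      child  = c("a", "b", "c", "d", "d", "e", "f"),
      parent = c("r", "r", "a", "a", "b", "b", "c"),
      stringsAsFactors = FALSE)
  )
  class(dag) <- "ontology_dag"
  dag
}

# a random workflow spec for emit-then-query property tests
random_workflow_spec <- function(seed, n_steps = NULL) {
  set.seed(seed)
  n <- n_steps %||% sample(2:6, 1)
  steps <- lapply(seq_len(n), function(i) {
    step_spec(sprintf("Step_rand_%02d", i),
              label = sprintf("Random step %d", i),
              kind = sample(c("manual", "script"), 1),
              language = sample(c("English", "R"), 1))
  })
  workflow_spec(id = sprintf("Plan_Random_Workflow_s%d", seed),
                version = "0.1", created = "2020-01-01",
                steps = steps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
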