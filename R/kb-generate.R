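#' Generator configuration for synthetic knowledge bases
#'
#' Defines the study conditions a synthetic knowledge base is drawn under.
#' Drugs, diseases and proteins are assigned to latent clusters; within a
#' cluster entities share modality prototypes (fingerprint bits, side
#' effects, targets, ontology annotations, description terms), perturbed at
#' rate `modality_noise`. Gold-standard associations link drug cluster c to
#' disease cluster c with probability `signal_strength`, and to a uniformly
#' chosen cluster otherwise — the planted signal the prediction method is
#' expected to recover.
#'
#' @param n_drugs,n_diseases,n_proteins entity counts.
#' @param fingerprint_length length F of the MACCS-like fingerprint bit
#'   space; fingerprints are subsets of `[0, F)`.
#' @param n_clusters number of latent drug/disease clusters.
#' @param signal_strength rho in `[0,1]`: probability a gold association
#'   respects cluster identity.
#' @param modality_noise per-feature perturbation rate in `[0,1]`.
#' @param associations_per_drug mean number of gold indications per drug.
#' @param n_side_effect_terms size of the side-effect vocabulary.
#' @param vocab_size size of the disease description vocabulary.
#' @param go_size,hpo_size number of terms in the GO-like and HPO-like
#'   ontologies.
#' @param seq_length protein sequence length.
#' @param seed integer seed; generation is a pure function of the config.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_drugs = 120, n_diseases = 80, n_proteins = 150,
                             fingerprint_length = 166, n_clusters = 10,
                             signal_strength = 0.9, modality_noise = 0.05,
                             associations_per_drug = 2,
                             n_side_effect_terms = 80, vocab_size = 300,
                             go_size = 200, hpo_size = 150, seq_length = 120,
                             seed = 1L) {
  cfg <- list(
    n_drugs = n_drugs, n_diseases = n_diseases, n_proteins = n_proteins,
    fingerprint_length = fingerprint_length, n_clusters = n_clusters,
    signal_strength = signal_strength, modality_noise = modality_noise,
    associations_per_drug = associations_per_drug,
    n_side_effect_terms = n_side_effect_terms, vocab_size = vocab_size,
    go_size = go_size, hpo_size = hpo_size, seq_length = seq_length,
    seed = as.integer(seed)
  )
  counts <- c("n_drugs", "n_diseases", "n_proteins", "fingerprint_length",
              "n_clusters", "n_side_effect_terms", "vocab_size", "go_size",
              "hpo_size", "seq_length")
  for (nm in counts) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] < 1) {
      stop_input("generator_config: '", nm, "' must be a positive count")
    }
  }
  for (nm in c("signal_strength", "modality_noise")) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      stop_input("generator_config: '", nm, "' must lie in [0, 1]")
    }
  }
  if (cfg$associations_per_drug <= 0) {
    stop_input("generator_config: 'associations_per_drug' must be positive")
  }
  if (cfg$n_clusters > min(cfg$n_drugs, cfg$n_diseases, cfg$n_proteins)) {
    stop_input("generator_config: more clusters than entities")
  }
  class(cfg) <- "generator_config"
  cfg
}

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","V","Y")

# Random is-a DAG: a guaranteed root chain (depth >= 4) plus random-parent
# tree edges, then ~10% extra is-a edges toward lower-index terms (keeps the
# graph acyclic). Term 1 is the root.
random_ontology_dag <- function(n_terms, prefix) {
  ids <- sprintf("%s:%04d", prefix, seq_len(n_terms))
  parent <- integer(n_terms)  # index of primary parent; 0 for root
  chain <- min(5L, n_terms)
  if (chain > 1) parent[2:chain] <- 1:(chain - 1L)
  if (n_terms > chain) {
    for (i in (chain + 1L):n_terms) parent[i] <- sample.int(i - 1L, 1L)
  }
  edges <- data.frame(
    child = ids[which(parent > 0)],
    parent = ids[parent[parent > 0]],
    stringsAsFactors = FALSE
  )
  n_extra <- ceiling(0.1 * n_terms)
  if (n_terms >= 3) {
    for (k in seq_len(n_extra)) {
      child <- sample(3:n_terms, 1L)
      extra_parent <- sample.int(child - 1L, 1L)
      if (extra_parent != parent[child]) {
        edges <- rbind(edges, data.frame(child = ids[child],
                                         parent = ids[extra_parent],
                                         stringsAsFactors = FALSE))
      }
    }
  }
  dag <- list(terms = ids, root = ids[1], edges = unique(edges))
  class(dag) <- "ontology_dag"
  dag
}

# parent list keyed by term id
dag_parents <- function(dag) {
  split(dag$edges$parent, factor(dag$edges$child, levels = dag$terms))
}

#' Ancestor sets of every term in a DAG
#'
#' @param dag an `ontology_dag`.
#' @return named list: term id -> character vector of ancestors including
#'   the term itself.
#' @export
dag_ancestors <- function(dag) {
  par <- dag_parents(dag)
  anc <- vector("list", length(dag$terms))
  names(anc) <- dag$terms
  # terms are generated so parents precede children in id order, but be
  # safe: iterative memoised climb
  get_anc <- function(t) {
    if (!is.null(anc[[t]])) return(anc[[t]])
    p <- par[[t]]
    res <- t
    if (length(p)) {
      for (q in p) res <- union(res, get_anc(q))
    }
    anc[[t]] <<- res
    res
  }
  for (t in dag$terms) get_anc(t)
  anc
}

dag_depth <- function(dag) {
  anc <- dag_ancestors(dag)
  max(lengths(anc))
}

# flip set membership over a universe: each prototype element dropped with
# prob noise, each non-member added with prob noise * |proto|/|universe|
# (keeps expected set size stable)
perturb_set <- function(proto, universe, noise) {
  keep <- proto[runif(length(proto)) >= noise]
  pool <- setdiff(universe, proto)
  p_add <- if (length(pool)) noise * length(proto) / length(pool) else 0
  add <- pool[runif(length(pool)) < p_add]
  out <- sort(union(keep, add))
  if (!length(out) && length(proto)) out <- sample(proto, 1L)
  out
}

mutate_sequence <- function(seq_chars, rate) {
  hit <- runif(length(seq_chars)) < rate
  if (any(hit)) seq_chars[hit] <- sample(AA20, sum(hit), replace = TRUE)
  seq_chars
}

#' Generate a synthetic knowledge base with planted signal
#'
#' Draws drugs, diseases, proteins, ontologies, a protein-protein
#' interaction network and a gold standard of drug-disease associations
#' under the cluster model described in [generator_config()]. Identical
#' config (including its seed) always yields the identical knowledge base.
#'
#' @param config a [generator_config()].
#' @return object of class `knowledge_base` with fields `drugs`,
#'   `diseases`, `proteins`, `ppi`, `go_dag`, `hpo_dag`, `vocab_size`,
#'   `gold`, `gen_seed`, `gen_config`, plus latent `drug_cluster` /
#'   `disease_cluster` labels retained for evaluation.
#' @export
generate_knowledge_base <- function(config = generator_config()) {
  if (!inherits(config, "generator_config")) {
    config <- do.call(generator_config, as.list(config))
  }
  with_seed(config$seed, {
    nc <- config$n_clusters
    noise <- config$modality_noise

    go_dag <- random_ontology_dag(config$go_size, "GO")
    hpo_dag <- random_ontology_dag(config$hpo_size, "HP")

    drug_cluster <- rep_len(seq_len(nc), config$n_drugs)
    disease_cluster <- rep_len(seq_len(nc), config$n_diseases)
    protein_cluster <- rep_len(seq_len(nc), config$n_proteins)

    # cluster prototypes
    fp_universe <- 0:(config$fingerprint_length - 1L)
    fp_proto <- lapply(seq_len(nc), function(c) {
      sort(sample(fp_universe, max(8L, rbinom(1, config$fingerprint_length, 0.25))))
    })
    se_universe <- sprintf("SE:%03d", seq_len(config$n_side_effect_terms))
    se_proto <- lapply(seq_len(nc), function(c) {
      sort(sample(se_universe, max(3L, rbinom(1, config$n_side_effect_terms, 0.12))))
    })
    # bias GO/HPO prototypes away from the shallow chain terms
    go_pool <- go_dag$terms[-seq_len(min(5L, length(go_dag$terms)))]
    go_proto <- lapply(seq_len(nc), function(c) sort(sample(go_pool, 6L)))
    hpo_pool <- hpo_dag$terms[-seq_len(min(5L, length(hpo_dag$terms)))]
    hpo_proto <- lapply(seq_len(nc), function(c) sort(sample(hpo_pool, 6L)))
    seq_proto <- lapply(seq_len(nc), function(c) {
      sample(AA20, config$seq_length, replace = TRUE)
    })
    vocab <- sprintf("TERM:%04d", seq_len(config$vocab_size))
    desc_proto <- lapply(seq_len(nc), function(c) {
      terms <- sample(config$vocab_size, 20L)
      counts <- rpois(20L, 3) + 1L
      stats::setNames(counts, vocab[terms])
    })

    protein_ids <- sprintf("P%04d", seq_len(config$n_proteins))
    proteins <- lapply(seq_len(config$n_proteins), function(i) {
      c <- protein_cluster[i]
      list(
        protein_id = protein_ids[i],
        sequence = paste(mutate_sequence(seq_proto[[c]], noise), collapse = ""),
        go_terms = perturb_set(go_proto[[c]], go_pool, noise)
      )
    })

    # PPI: dense within protein clusters, sparse across
    edges <- list()
    for (i in seq_len(config$n_proteins - 1L)) {
      js <- (i + 1L):config$n_proteins
      same <- protein_cluster[js] == protein_cluster[i]
      p <- ifelse(same, 0.3, 0.01)
      hit <- js[runif(length(js)) < p]
      if (length(hit)) {
        edges[[length(edges) + 1L]] <- data.frame(
          a = protein_ids[i], b = protein_ids[hit], stringsAsFactors = FALSE)
      }
    }
    ppi <- if (length(edges)) do.call(rbind, edges) else {
      data.frame(a = character(), b = character(), stringsAsFactors = FALSE)
    }

    drug_ids <- sprintf("DR%04d", seq_len(config$n_drugs))
    drugs <- lapply(seq_len(config$n_drugs), function(i) {
      c <- drug_cluster[i]
      own <- protein_ids[protein_cluster == c]
      n_t <- sample(1:3, 1L)
      targets <- sample(own, min(n_t, length(own)))
      # with prob noise per target, swap for a random protein
      swap <- runif(length(targets)) < noise
      if (any(swap)) targets[swap] <- sample(protein_ids, sum(swap))
      list(
        drug_id = drug_ids[i],
        fingerprint = perturb_set(fp_proto[[c]], fp_universe, noise),
        side_effects = perturb_set(se_proto[[c]], se_universe, noise),
        targets = sort(unique(targets))
      )
    })

    disease_ids <- sprintf("DI%04d", seq_len(config$n_diseases))
    diseases <- lapply(seq_len(config$n_diseases), function(i) {
      c <- disease_cluster[i]
      proto <- desc_proto[[c]]
      # perturb counts; occasionally substitute a vocabulary term
      counts <- pmax(proto + rpois(length(proto), noise * 2) -
                       rpois(length(proto), noise * 2), 0L)
      swap <- runif(length(counts)) < noise
      nm <- names(counts)
      if (any(swap)) nm[swap] <- sample(vocab, sum(swap))
      keep <- counts > 0
      if (!any(keep)) { keep[1] <- TRUE; counts[1] <- 1L }
      vec <- stats::setNames(as.integer(counts[keep]), nm[keep])
      vec <- tapply(vec, names(vec), sum)  # merge duplicated swapped terms
      list(
        disease_id = disease_ids[i],
        phenotype_terms = perturb_set(hpo_proto[[c]], hpo_pool, noise),
        description_vector = stats::setNames(as.integer(vec), names(vec))
      )
    })

    # gold standard: planted cluster-respecting associations
    pairs <- character(0)
    gold_d <- character(0); gold_s <- character(0)
    for (i in seq_len(config$n_drugs)) {
      n_a <- max(1L, rpois(1L, config$associations_per_drug))
      for (k in seq_len(n_a)) {
        cl <- if (runif(1) < config$signal_strength) drug_cluster[i] else
          sample.int(nc, 1L)
        cand <- disease_ids[disease_cluster == cl]
        if (!length(cand)) next
        s <- sample(cand, 1L)
        key <- paste(drug_ids[i], s)
        if (!(key %in% pairs)) {
          pairs <- c(pairs, key)
          gold_d <- c(gold_d, drug_ids[i]); gold_s <- c(gold_s, s)
        }
      }
    }
    gold <- data.frame(drug_id = gold_d, disease_id = gold_s,
                       stringsAsFactors = FALSE)

    kb <- list(
      drugs = stats::setNames(drugs, drug_ids),
      diseases = stats::setNames(diseases, disease_ids),
      proteins = stats::setNames(proteins, protein_ids),
      ppi = ppi,
      go_dag = go_dag,
      hpo_dag = hpo_dag,
      vocab_size = config$vocab_size,
      gold = gold,
      drug_cluster = stats::setNames(drug_cluster, drug_ids),
      disease_cluster = stats::setNames(disease_cluster, disease_ids),
      protein_cluster = stats::setNames(protein_cluster, protein_ids),
      gen_seed = config$seed,
      gen_config = config
    )
    class(kb) <- "knowledge_base"
    validate_knowledge_base(kb)
    kb
  })
}

#' Validate knowledge-base invariants
#'
#' Checks referential integrity: drug targets resolve to proteins, ontology
#' annotations resolve to their DAGs, gold pairs reference existing entities
#' and contain no duplicates, and the PPI graph is simple.
#'
#' @param kb a `knowledge_base`.
#' @return `kb`, invisibly; errors on violation.
#' @export
validate_knowledge_base <- function(kb) {
  stopifnot(inherits(kb, "knowledge_base"))
  pid <- names(kb$proteins)
  for (d in kb$drugs) {
    if (!all(d$targets %in% pid)) {
      stop_input("knowledge base: drug ", d$drug_id, " has unresolved targets")
    }
  }
  for (p in kb$proteins) {
    if (!nzchar(p$sequence)) stop_input("knowledge base: empty sequence for ", p$protein_id)
    if (!all(p$go_terms %in% kb$go_dag$terms)) {
      stop_input("knowledge base: GO terms of ", p$protein_id, " outside the DAG")
    }
  }
  for (s in kb$diseases) {
    if (!all(s$phenotype_terms %in% kb$hpo_dag$terms)) {
      stop_input("knowledge base: phenotype terms of ", s$disease_id, " outside the DAG")
    }
    if (!length(s$description_vector) || all(s$description_vector == 0)) {
      stop_input("knowledge base: empty description vector for ", s$disease_id)
    }
  }
  if (nrow(kb$ppi)) {
    if (any(kb$ppi$a == kb$ppi$b)) stop_input("knowledge base: PPI self-loop")
    if (!all(c(kb$ppi$a, kb$ppi$b) %in% pid)) {
      stop_input("knowledge base: PPI node outside the protein set")
    }
    key <- paste(pmin(kb$ppi$a, kb$ppi$b), pmax(kb$ppi$a, kb$ppi$b))
    if (anyDuplicated(key)) stop_input("knowledge base: duplicate PPI edge")
  }
  if (anyDuplicated(paste(kb$gold$drug_id, kb$gold$disease_id))) {
    stop_input("knowledge base: duplicate gold pair")
  }
  if (!all(kb$gold$drug_id %in% names(kb$drugs)) ||
      !all(kb$gold$disease_id %in% names(kb$diseases))) {
    stop_input("knowledge base: gold pair references unknown entity")
  }
  invisible(kb)
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat("<knowledge_base>\n",
      "  drugs:    ", length(x$drugs), "\n",
      "  diseases: ", length(x$diseases), "\n",
      "  proteins: ", length(x$proteins), " (", nrow(x$ppi), " PPI edges)\n",
      "  gold:     ", nrow(x$gold), " drug-disease associations\n",
      "  ontologies: GO-like ", length(x$go_dag$terms), " terms, HPO-like ",
      length(x$hpo_dag$terms), " terms\n", sep = "")
  invisible(x)
}
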