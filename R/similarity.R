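#' Jaccard (Tanimoto) similarity of two finite sets
#'
#' Used for the chemical-fingerprint and shared-side-effect drug measures.
#'
#' @param a,b vectors interpreted as sets.
#' @return `|a & b| / |a | b|`; 0 when both sets are empty.
#' @export
jaccard_similarity <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Alignment scoring scheme
#'
#' @param substitution_matrix name of a substitution matrix shipped with
#'   Biostrings (default BLOSUM62).
#' @param gap_open,gap_extend positive gap penalties.
#' @return object of class `alignment_scoring`.
#' @export
alignment_scoring <- function(substitution_matrix = "BLOSUM62",
                              gap_open = 10, gap_extend = 0.5) {
  if (gap_open <= 0 || gap_extend <= 0) {
    stop_input("alignment_scoring: gap penalties must be positive")
  }
  structure(list(substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "alignment_scoring")
}

get_submat <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

sw_score <- function(patterns, subject, scoring) {
  Biostrings::pairwiseAlignment(
    pattern = patterns, subject = subject, type = "local",
    substitutionMatrix = get_submat(scoring$substitution_matrix),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
    scoreOnly = TRUE
  )
}

#' Normalised Smith-Waterman similarity of two protein sequences
#'
#' Optimal local-alignment score normalised by the geometric mean of the
#' self-alignment scores: `SW(s1,s2) / sqrt(SW(s1,s1) * SW(s2,s2))`, clipped
#' to `[0,1]`. Scores that never go positive yield 0.
#'
#' @param s1,s2 nonempty amino-acid strings.
#' @param scoring an [alignment_scoring()].
#' @return similarity in `[0,1]`.
#' @export
normalized_local_alignment <- function(s1, s2, scoring = alignment_scoring()) {
  if (!nzchar(s1) || !nzchar(s2)) stop_input("normalized_local_alignment: empty sequence")
  s12 <- max(0, sw_score(s1, s2, scoring))
  if (s12 == 0) return(0)
  s11 <- sw_score(s1, s1, scoring)
  s22 <- sw_score(s2, s2, scoring)
  clip01(s12 / sqrt(s11 * s22))
}

#' Information content of ontology terms from an annotation corpus
#'
#' Entity annotations are propagated to all ancestors; a term's information
#' content is `-ln(count(term) / count(root))` in natural-log units, where
#' `count` is the number of entities annotated to the term or any
#' descendant. Terms with zero annotation receive a pseudo-count of 1.
#'
#' @param dag an `ontology_dag`.
#' @param annotations named list: entity id -> character vector of term ids.
#' @return named numeric vector of information contents (class `ic_map`).
#' @export
information_content <- function(dag, annotations) {
  anc <- dag_ancestors(dag)
  counts <- stats::setNames(numeric(length(dag$terms)), dag$terms)
  for (terms in annotations) {
    if (!length(terms)) next
    if (!all(terms %in% dag$terms)) {
      stop_input("information_content: annotation term outside the DAG: ",
                 paste(setdiff(terms, dag$terms), collapse = ", "))
    }
    hit <- unique(unlist(anc[terms], use.names = FALSE))
    counts[hit] <- counts[hit] + 1
  }
  n_root <- counts[[dag$root]]
  if (n_root == 0) n_root <- 1
  counts[counts == 0] <- 1
  ic <- -log(counts / n_root)
  ic[ic < 0] <- 0
  class(ic) <- "ic_map"
  ic
}

# max-IC of a common ancestor for every term pair, as a dense matrix
mica_ic_matrix <- function(dag, ic) {
  anc <- dag_ancestors(dag)
  n <- length(dag$terms)
  M <- matrix(0, n, n, dimnames = list(dag$terms, dag$terms))
  # terms sorted by IC ascending: later updates overwrite with larger IC
  for (a in dag$terms[order(unclass(ic)[dag$terms])]) {
    desc <- dag$terms[vapply(anc, function(s) a %in% s, TRUE)]
    M[desc, desc] <- pmax(M[desc, desc], ic[[a]])
  }
  M
}

bma_from_matrix <- function(S, tA, tB) {
  sub <- S[tA, tB, drop = FALSE]
  (mean(apply(sub, 1, max)) + mean(apply(sub, 2, max))) / 2
}

#' Resnik-style best-match-average semantic similarity of two term sets
#'
#' Pairwise term similarity is the information content of the
#' most-informative common ancestor, normalised by the maximum information
#' content in the corpus; set similarity is the best-match average (the mean
#' over both directions of each term's best pairwise match).
#'
#' @param tA,tB character vectors of term ids within `dag`.
#' @param dag an `ontology_dag`.
#' @param ic an `ic_map` from [information_content()].
#' @return similarity in `[0,1]`; 0 with a warning when a set is empty.
#' @export
semantic_set_similarity <- function(tA, tB, dag, ic) {
  if (!length(tA) || !length(tB)) {
    warning("semantic_set_similarity: empty term set; returning 0")
    return(0)
  }
  if (!all(c(tA, tB) %in% dag$terms)) {
    stop_input("semantic_set_similarity: term outside the DAG")
  }
  mx <- max(unclass(ic))
  if (mx == 0) return(0)
  anc <- dag_ancestors(dag)
  pair_sim <- function(t1, t2) {
    common <- intersect(anc[[t1]], anc[[t2]])
    max(unclass(ic)[common]) / mx
  }
  sub <- outer(tA, tB, Vectorize(pair_sim))
  clip01((mean(apply(sub, 1, max)) + mean(apply(sub, 2, max))) / 2)
}

#' Network closeness of two protein target sets
#'
#' Pairwise protein similarity is `exp(-b * d)` with `d` the unweighted
#' shortest-path length in the interaction network (`d = 0` for a shared
#' protein, disconnected pairs score 0); the set score takes the maximum
#' over target pairs.
#'
#' @param net data frame of undirected edges (`a`, `b`) or an igraph object.
#' @param pA,pB character vectors of protein ids.
#' @param decay positive decay rate `b` (default 1).
#' @return similarity in `[0,1]`; 0 with a warning when a set is empty.
#' @export
ppi_closeness <- function(net, pA, pB, decay = 1) {
  if (decay <= 0) stop_input("ppi_closeness: decay must be positive")
  if (!length(pA) || !length(pB)) {
    warning("ppi_closeness: empty target set; returning 0")
    return(0)
  }
  if (length(intersect(pA, pB))) return(1)
  gr <- if (inherits(net, "igraph")) net else {
    igraph::graph_from_data_frame(net, directed = FALSE,
                                  vertices = unique(c(net$a, net$b, pA, pB)))
  }
  vs <- igraph::V(gr)$name
  pA <- intersect(pA, vs); pB <- intersect(pB, vs)
  if (!length(pA) || !length(pB)) return(0)
  d <- igraph::distances(gr, v = pA, to = pB)
  dmin <- min(d)
  if (!is.finite(dmin)) return(0)
  clip01(exp(-decay * dmin))
}

#' Cosine similarity of two nonnegative description vectors
#'
#' @param vA,vB named count vectors over the same description vocabulary
#'   (sparse: absent names count as 0).
#' @return cosine in `[0,1]`; 0 when either vector is all-zero.
#' @export
description_cosine <- function(vA, vB) {
  nA <- sqrt(sum(as.numeric(vA)^2)); nB <- sqrt(sum(as.numeric(vB)^2))
  if (nA == 0 || nB == 0) return(0)
  shared <- intersect(names(vA), names(vB))
  if (!length(shared)) return(0)
  clip01(sum(as.numeric(vA[shared]) * as.numeric(vB[shared])) / (nA * nB))
}
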