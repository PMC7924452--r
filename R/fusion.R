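#' Fusion configuration
#'
#' Controls how a drug-side and a disease-side similarity are combined into
#' one feature: the weighted geometric mean `S_drug^w * S_disease^(1-w)` is
#' evaluated against every known association and aggregated.
#'
#' @param w drug-side exponent, in the open interval (0, 1). Default 0.5
#'   (the plain geometric mean).
#' @param aggregation `"max"` (default; strongest evidence) or `"mean"`.
#' @param exclude_self drop the candidate pair itself from the evidence set
#'   — the leakage guard for features of known positives (default `TRUE`).
#' @return object of class `fusion_config`.
#' @export
fusion_config <- function(w = 0.5, aggregation = c("max", "mean"),
                          exclude_self = TRUE) {
  if (!is.numeric(w) || length(w) != 1 || w <= 0 || w >= 1) {
    stop_input("fusion_config: w must lie strictly between 0 and 1")
  }
  aggregation <- match.arg(aggregation)
  structure(list(w = w, aggregation = aggregation,
                 exclude_self = isTRUE(exclude_self)),
            class = "fusion_config")
}

#' Fused similarity feature for one drug-disease pair
#'
#' Aggregates, over the known associations `(d', s')`, the weighted
#' geometric mean of the drug-drug similarity `S_i(d, d')` and the
#' disease-disease similarity `S_j(s, s')`. An empty evidence set yields 0.
#'
#' @param d,s drug and disease identifiers.
#' @param drug_sim,disease_sim `similarity_matrix` objects.
#' @param known data frame of known associations (`drug_id`, `disease_id`).
#' @param cfg a [fusion_config()].
#' @return fused value in `[0,1]`.
#' @export
fuse_pair <- function(d, s, drug_sim, disease_sim, known, cfg = fusion_config()) {
  if (!d %in% rownames(drug_sim)) stop_input("fuse_pair: unknown drug id ", d)
  if (!s %in% rownames(disease_sim)) stop_input("fuse_pair: unknown disease id ", s)
  if (!all(known$drug_id %in% rownames(drug_sim)) ||
      !all(known$disease_id %in% rownames(disease_sim))) {
    stop_input("fuse_pair: known association references unknown entity")
  }
  cand <- known
  if (cfg$exclude_self) {
    cand <- cand[!(cand$drug_id == d & cand$disease_id == s), , drop = FALSE]
  }
  if (!nrow(cand)) return(0)
  v <- drug_sim[d, cand$drug_id]^cfg$w *
    disease_sim[s, cand$disease_id]^(1 - cfg$w)
  clip01(if (cfg$aggregation == "max") max(v) else mean(v))
}

feature_column_names <- function() {
  as.vector(t(outer(DRUG_MEASURES, DISEASE_MEASURES, paste, sep = "_")))
}

#' Build the 10-feature table for a set of drug-disease pairs
#'
#' One row per requested pair; the 10 feature columns cross the five drug
#' measures with the two disease measures in the fixed order
#' `chemical_mesh, chemical_hpo, side_effect_mesh, ..., ppi_hpo`. Each cell
#' is [fuse_pair()] against the supplied known-association evidence set,
#' vectorised over pairs.
#'
#' @param matrices list of 7 `similarity_matrix` objects from
#'   [build_similarity_matrices()].
#' @param pairs data frame with columns `drug_id`, `disease_id` and
#'   optionally `label` (0/1).
#' @param known data frame of known associations used as fusion evidence.
#' @param cfg a [fusion_config()].
#' @return data frame of class `feature_table`: key columns, 10 features,
#'   and `label` when supplied.
#' @export
build_feature_table <- function(matrices, pairs, known, cfg = fusion_config()) {
  stopifnot(all(c("drug_id", "disease_id") %in% names(pairs)))
  if (anyDuplicated(paste(pairs$drug_id, pairs$disease_id))) {
    stop_input("build_feature_table: duplicate pair requested")
  }
  drug_ids <- rownames(matrices$chemical)
  disease_ids <- rownames(matrices$mesh)
  if (!all(pairs$drug_id %in% drug_ids) || !all(pairs$disease_id %in% disease_ids)) {
    stop_input("build_feature_table: pair references unknown entity")
  }
  if (nrow(known)) {
    if (!all(known$drug_id %in% drug_ids) || !all(known$disease_id %in% disease_ids)) {
      stop_input("build_feature_table: known association references unknown entity")
    }
  }
  n <- nrow(pairs)
  out <- pairs[, c("drug_id", "disease_id"), drop = FALSE]
  cols <- feature_column_names()
  if (!nrow(known)) {
    for (cn in cols) out[[cn]] <- 0
  } else {
    # self-mask: requested pair equals evidence pair
    self_mask <- outer(paste(pairs$drug_id, pairs$disease_id),
                       paste(known$drug_id, known$disease_id), `==`)
    for (dm in DRUG_MEASURES) {
      A <- unclass(matrices[[dm]])[pairs$drug_id, known$drug_id, drop = FALSE]^cfg$w
      for (sm in DISEASE_MEASURES) {
        B <- unclass(matrices[[sm]])[pairs$disease_id, known$disease_id, drop = FALSE]^(1 - cfg$w)
        V <- A * B
        if (cfg$exclude_self && any(self_mask)) V[self_mask] <- NA
        val <- if (cfg$aggregation == "max") {
          suppressWarnings(apply(V, 1, max, na.rm = TRUE))
        } else {
          rowMeans(V, na.rm = TRUE)
        }
        val[!is.finite(val) | is.nan(val)] <- 0  # empty evidence set
        out[[paste(dm, sm, sep = "_")]] <- clip01(val)
      }
    }
  }
  if ("label" %in% names(pairs)) out$label <- pairs$label
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Write / read a feature table as CSV
#' @param ft a `feature_table`.
#' @param path CSV file path.
#' @return `path` invisibly for the writer; a `feature_table` for the reader.
#' @export
write_feature_table <- function(ft, path) {
  utils::write.csv(as.data.frame(ft), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  ft <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  class(ft) <- c("feature_table", "data.frame")
  ft
}
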