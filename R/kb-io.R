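#' Write a knowledge base to a plain-text bundle
#'
#' Layout: `manifest.json` (scalar metadata, ontologies, description
#' vectors, gold standard), `drugs.csv`, `diseases.csv`, `ppi.tsv`,
#' `annotations.tsv` (disease-phenotype links) and `proteins.fasta`.
#' Set-valued columns are `|`-separated. [read_kb()] round-trips the bundle.
#'
#' @param kb a `knowledge_base`.
#' @param dir directory to create/populate.
#' @return `dir`, invisibly.
#' @export
write_kb <- function(kb, dir) {
  validate_knowledge_base(kb)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  drugs <- data.frame(
    drug_id = names(kb$drugs),
    fingerprint = vapply(kb$drugs, function(d) paste(d$fingerprint, collapse = "|"), ""),
    side_effects = vapply(kb$drugs, function(d) paste(d$side_effects, collapse = "|"), ""),
    targets = vapply(kb$drugs, function(d) paste(d$targets, collapse = "|"), ""),
    stringsAsFactors = FALSE
  )
  utils::write.csv(drugs, file.path(dir, "drugs.csv"), row.names = FALSE)
  diseases <- data.frame(
    disease_id = names(kb$diseases),
    phenotype_terms = vapply(kb$diseases, function(s) paste(s$phenotype_terms, collapse = "|"), ""),
    stringsAsFactors = FALSE
  )
  utils::write.csv(diseases, file.path(dir, "diseases.csv"), row.names = FALSE)
  utils::write.table(kb$ppi, file.path(dir, "ppi.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  ann <- do.call(rbind, lapply(kb$diseases, function(s) {
    if (!length(s$phenotype_terms)) return(NULL)
    data.frame(disease_id = s$disease_id, term_id = s$phenotype_terms,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(ann, file.path(dir, "annotations.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  seqs <- Biostrings::AAStringSet(vapply(kb$proteins, `[[`, "", "sequence"))
  names(seqs) <- names(kb$proteins)
  Biostrings::writeXStringSet(seqs, file.path(dir, "proteins.fasta"))
  manifest <- list(
    format = "repurpose-kb/1",
    gen_seed = kb$gen_seed,
    gen_config = unclass(kb$gen_config),
    vocab_size = kb$vocab_size,
    go_dag = list(terms = kb$go_dag$terms, root = kb$go_dag$root,
                  edges = kb$go_dag$edges),
    hpo_dag = list(terms = kb$hpo_dag$terms, root = kb$hpo_dag$root,
                   edges = kb$hpo_dag$edges),
    protein_go = lapply(kb$proteins, `[[`, "go_terms"),
    description_vectors = lapply(kb$diseases, function(s) as.list(s$description_vector)),
    gold = kb$gold,
    drug_cluster = as.list(kb$drug_cluster),
    disease_cluster = as.list(kb$disease_cluster),
    protein_cluster = as.list(kb$protein_cluster)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(dir)
}

split_bar <- function(x) if (!nzchar(x)) character(0) else strsplit(x, "|", fixed = TRUE)[[1]]

#' Read a knowledge-base bundle written by [write_kb()]
#'
#' @param dir bundle directory.
#' @return a `knowledge_base`.
#' @export
read_kb <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  drugs_df <- utils::read.csv(file.path(dir, "drugs.csv"), stringsAsFactors = FALSE,
                              colClasses = "character")
  diseases_df <- utils::read.csv(file.path(dir, "diseases.csv"), stringsAsFactors = FALSE,
                                 colClasses = "character")
  ppi <- utils::read.delim(file.path(dir, "ppi.tsv"), stringsAsFactors = FALSE,
                           colClasses = "character")
  seqs <- Biostrings::readAAStringSet(file.path(dir, "proteins.fasta"))
  mk_dag <- function(d) {
    # manifest data frames serialize as arrays of row objects
    edges <- data.frame(
      child = vapply(d$edges, function(e) e$child, ""),
      parent = vapply(d$edges, function(e) e$parent, ""),
      stringsAsFactors = FALSE
    )
    rownames(edges) <- NULL
    dag <- list(terms = unlist(d$terms), root = d$root, edges = edges)
    class(dag) <- "ontology_dag"
    dag
  }
  drugs <- lapply(seq_len(nrow(drugs_df)), function(i) {
    list(drug_id = drugs_df$drug_id[i],
         fingerprint = as.integer(split_bar(drugs_df$fingerprint[i])),
         side_effects = split_bar(drugs_df$side_effects[i]),
         targets = split_bar(drugs_df$targets[i]))
  })
  names(drugs) <- drugs_df$drug_id
  diseases <- lapply(seq_len(nrow(diseases_df)), function(i) {
    id <- diseases_df$disease_id[i]
    dv <- man$description_vectors[[id]]
    list(disease_id = id,
         phenotype_terms = split_bar(diseases_df$phenotype_terms[i]),
         description_vector = stats::setNames(as.integer(unlist(dv)), names(dv)))
  })
  names(diseases) <- diseases_df$disease_id
  proteins <- lapply(names(seqs), function(id) {
    list(protein_id = id,
         sequence = as.character(seqs[[id]]),
         go_terms = unlist(man$protein_go[[id]]) %||% character(0))
  })
  names(proteins) <- names(seqs)
  gold <- data.frame(
    drug_id = vapply(man$gold, function(r) r$drug_id, ""),
    disease_id = vapply(man$gold, function(r) r$disease_id, ""),
    stringsAsFactors = FALSE
  )
  rownames(gold) <- NULL
  cfg <- man$gen_config
  cfg <- do.call(generator_config, cfg)
  kb <- list(
    drugs = drugs, diseases = diseases, proteins = proteins,
    ppi = ppi, go_dag = mk_dag(man$go_dag), hpo_dag = mk_dag(man$hpo_dag),
    vocab_size = man$vocab_size, gold = gold,
    drug_cluster = stats::setNames(as.integer(unlist(man$drug_cluster)), names(man$drug_cluster)),
    disease_cluster = stats::setNames(as.integer(unlist(man$disease_cluster)), names(man$disease_cluster)),
    protein_cluster = stats::setNames(as.integer(unlist(man$protein_cluster)), names(man$protein_cluster)),
    gen_seed = man$gen_seed,
    gen_config = cfg
  )
  class(kb) <- "knowledge_base"
  validate_knowledge_base(kb)
  kb
}

read_table_text <- function(text) {
  # accepts a file path, a single string with newlines, or a character
  # vector of lines
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    return(readLines(text, warn = FALSE))
  }
  unlist(strsplit(text, "\n", fixed = TRUE))
}

#' Load a drug-indication gold standard from tab-separated text
#'
#' Expects two tab-separated columns (drug id, disease id); a header row is
#' skipped when its first field does not look like a data identifier
#' (matches common header words case-insensitively). Duplicate rows are
#' collapsed: the result has set semantics.
#'
#' @param text file path, single string, or character vector of lines.
#' @return data frame with columns `drug_id`, `disease_id` (deduplicated).
#' @export
load_gold_standard_table <- function(text) {
  lines <- read_table_text(text)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(drug_id = character(), disease_id = character(),
                      stringsAsFactors = FALSE))
  }
  first <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(first) >= 2 &&
      grepl("drug|disease|omim|id|name", first[1], ignore.case = TRUE) &&
      grepl("drug|disease|omim|id|name|indication", first[2], ignore.case = TRUE)) {
    lines <- lines[-1]
  }
  out <- matrix(NA_character_, nrow = length(lines), ncol = 2)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2 || !nzchar(trimws(f[1])) || !nzchar(trimws(f[2]))) {
      stop_input("gold standard parse error at line ", i,
                 ": expected drug and disease columns")
    }
    out[i, ] <- trimws(f[1:2])
  }
  df <- unique(data.frame(drug_id = out[, 1], disease_id = out[, 2],
                          stringsAsFactors = FALSE))
  rownames(df) <- NULL
  df
}

#' Load a protein-protein interaction table
#'
#' Two tab-separated interactor columns; edges are undirected and
#' deduplicated, self-loop rows are dropped with a warning.
#'
#' @param text file path, single string, or character vector of lines.
#' @param header skip a first header row when `TRUE`.
#' @return data frame with columns `a`, `b` (one row per undirected edge).
#' @export
load_ppi_table <- function(text, header = FALSE) {
  lines <- read_table_text(text)
  lines <- lines[nzchar(trimws(lines))]
  if (header && length(lines)) lines <- lines[-1]
  if (!length(lines)) {
    return(data.frame(a = character(), b = character(), stringsAsFactors = FALSE))
  }
  a <- character(0); b <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2 || !nzchar(trimws(f[1])) || !nzchar(trimws(f[2]))) {
      stop_input("PPI parse error at line ", i, ": expected two interactor columns")
    }
    a <- c(a, trimws(f[1])); b <- c(b, trimws(f[2]))
  }
  loop <- a == b
  if (any(loop)) {
    warning(sum(loop), " self-loop row(s) dropped from PPI table")
    a <- a[!loop]; b <- b[!loop]
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  keep <- !duplicated(paste(lo, hi))
  data.frame(a = lo[keep], b = hi[keep], stringsAsFactors = FALSE)
}

#' Load disease-phenotype annotations
#'
#' Tab-separated rows of (disease id, term id); returns a set-valued map.
#'
#' @param text file path, single string, or character vector of lines.
#' @param header skip a first header row when `TRUE`.
#' @return named list: disease id -> character vector of term ids.
#' @export
load_phenotype_annotations <- function(text, header = FALSE) {
  lines <- read_table_text(text)
  lines <- lines[nzchar(trimws(lines))]
  if (header && length(lines)) lines <- lines[-1]
  if (!length(lines)) return(stats::setNames(list(), character(0)))
  dis <- character(0); term <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2 || !nzchar(trimws(f[1])) || !nzchar(trimws(f[2]))) {
      stop_input("annotation parse error at line ", i,
                 ": expected disease and term columns")
    }
    dis <- c(dis, trimws(f[1])); term <- c(term, trimws(f[2]))
  }
  lapply(split(term, dis), function(x) sort(unique(x)))
}

#' Emit the FAIRified RDF representation of knowledge-base inputs
#'
#' Each PPI edge becomes an interaction node carrying the Bio2RDF
#' `interactor_a`/`interactor_b` properties; each disease-phenotype link is
#' a SIO has-phenotype (SIO_001279) triple on a SIO disease (SIO_010299);
#' the graph carries dataset-level metadata (title, license, created).
#'
#' @param kb a `knowledge_base`.
#' @param base IRI base for minted nodes.
#' @return an `rdf_graph`.
#' @export
emit_input_rdf <- function(kb, base = "https://w3id.org/fair/plex") {
  validate_knowledge_base(kb)
  pf <- default_prefixes(base)
  pf[["kbr"]] <- paste0(base, "/kb#")
  g <- rdf_graph(pf)
  ds <- "kbr:Dataset_input_collection"
  g <- rdf_add(g, ds, "rdf:type", "dcat:Dataset")
  g <- rdf_add(g, ds, "dc:title", "Synthetic drug repurposing input collection", o_iri = FALSE)
  g <- rdf_add(g, ds, "dc:license", "https://creativecommons.org/licenses/by/4.0/")
  g <- rdf_add(g, ds, "dc:created", format(Sys.Date()), o_iri = FALSE, dt = "xsd:date")
  if (nrow(kb$ppi)) {
    node <- sprintf("kbr:Interaction_%s_%s", kb$ppi$a, kb$ppi$b)
    g <- rdf_add(g, node, "rdf:type", "sio:SIO_000897")  # association
    g <- rdf_add(g, node, "bio2rdf:interactor_a", paste0("kbr:Protein_", kb$ppi$a))
    g <- rdf_add(g, node, "bio2rdf:interactor_b", paste0("kbr:Protein_", kb$ppi$b))
  }
  for (s in kb$diseases) {
    dnode <- paste0("kbr:Disease_", s$disease_id)
    g <- rdf_add(g, dnode, "rdf:type", "sio:SIO_010299")
    if (length(s$phenotype_terms)) {
      g <- rdf_add(g, dnode, "sio:SIO_001279",
                   paste0("kbr:Phenotype_", gsub(":", "_", s$phenotype_terms)))
    }
  }
  g
}
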