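#' In-memory RDF graphs
#'
#' The provenance and competency modules operate on a light-weight triple
#' store: a data frame of (subject, predicate, object) rows with expanded
#' IRIs, plus a prefix map used only for Turtle (de)serialisation. Blank
#' nodes are never minted, so two graphs are isomorphic exactly when their
#' expanded triple sets are equal.
#'
#' @param prefixes named character vector mapping prefix labels to namespace
#'   IRIs. Defaults to [default_prefixes()].
#' @return an object of class `rdf_graph`.
#' @export
rdf_graph <- function(prefixes = default_prefixes()) {
  g <- list(
    triples = data.frame(
      s = character(), p = character(), o = character(),
      o_iri = logical(), dt = character(),
      stringsAsFactors = FALSE
    ),
    prefixes = prefixes
  )
  class(g) <- "rdf_graph"
  g
}

#' Default namespace bindings
#'
#' Canonical URIs for the vocabularies the provenance emitters use. The
#' `bpmn` and `opredict` namespaces have no canonical URI and are minted
#' under a configurable base.
#'
#' @param base base IRI for minted namespaces.
#' @return named character vector of prefix -> namespace IRI.
#' @export
default_prefixes <- function(base = "https://w3id.org/fair/plex") {
  c(
    rdf      = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    rdfs     = "http://www.w3.org/2000/01/rdf-schema#",
    xsd      = "http://www.w3.org/2001/XMLSchema#",
    `p-plan` = "http://purl.org/net/p-plan#",
    prov     = "http://www.w3.org/ns/prov#",
    dul      = "http://www.ontologydesignpatterns.org/ont/dul/DUL.owl#",
    pwo      = "http://purl.org/spar/pwo/",
    dcat     = "http://www.w3.org/ns/dcat#",
    mls      = "http://www.w3.org/ns/mls#",
    opmw     = "http://www.opmw.org/ontology/",
    edam     = "http://edamontology.org/",
    dc       = "http://purl.org/dc/terms/",
    sio      = "http://semanticscience.org/resource/",
    bio2rdf  = "http://bio2rdf.org/bio2rdf_vocabulary:",
    bpmn     = paste0(base, "/bpmn#"),
    opredict = paste0(base, "/opredict#")
  )
}

is_absolute_iri <- function(x) grepl("^[A-Za-z][A-Za-z0-9+.-]*://", x) | grepl("^urn:", x)

#' Expand a CURIE against a prefix map
#'
#' Strings that already look like absolute IRIs pass through unchanged.
#'
#' @param x character vector of CURIEs or absolute IRIs.
#' @param prefixes named character vector of bindings.
#' @return character vector of absolute IRIs.
#' @export
expand_iri <- function(x, prefixes) {
  out <- x
  curie <- !is_absolute_iri(x) & grepl(":", x, fixed = TRUE)
  if (any(curie)) {
    pfx <- sub(":.*$", "", x[curie])
    local <- sub("^[^:]*:", "", x[curie])
    unknown <- !(pfx %in% names(prefixes))
    if (any(unknown)) {
      stop_input("unknown prefix: ", paste(unique(pfx[unknown]), collapse = ", "))
    }
    out[curie] <- paste0(prefixes[pfx], local)
  }
  out
}

compact_iri <- function(x, prefixes) {
  # longest-namespace match; fall back to <iri> form handled by serializer
  out <- rep(NA_character_, length(x))
  ord <- order(nchar(prefixes), decreasing = TRUE)
  for (i in ord) {
    ns <- prefixes[[i]]
    hit <- is.na(out) & startsWith(x, ns)
    if (any(hit)) {
      local <- substring(x[hit], nchar(ns) + 1L)
      ok <- grepl("^[A-Za-z0-9_]([A-Za-z0-9_.-]*[A-Za-z0-9_-])?$", local) | local == ""
      idx <- which(hit)[ok]
      if (length(idx)) {
        out[idx] <- paste0(names(prefixes)[i], ":",
                           substring(x[idx], nchar(ns) + 1L))
      }
    }
  }
  out
}

#' Add triples to a graph
#'
#' Vectorised over `s`, `p`, `o`. Subjects and predicates are IRIs (CURIEs
#' are expanded against the graph's prefix map); objects are IRIs when
#' `o_iri` is `TRUE`, literals otherwise, with an optional datatype.
#'
#' @param g an `rdf_graph`.
#' @param s,p,o subject, predicate, object.
#' @param o_iri logical; is the object an IRI?
#' @param dt optional datatype IRI/CURIE for literal objects.
#' @return the augmented `rdf_graph`.
#' @export
rdf_add <- function(g, s, p, o, o_iri = TRUE, dt = NA_character_) {
  stopifnot(inherits(g, "rdf_graph"))
  n <- max(length(s), length(p), length(o))
  if (n == 0) return(g)
  s <- expand_iri(rep_len(as.character(s), n), g$prefixes)
  p <- expand_iri(rep_len(as.character(p), n), g$prefixes)
  o <- rep_len(as.character(o), n)
  o_iri <- rep_len(o_iri, n)
  dt <- rep_len(as.character(dt), n)
  o[o_iri] <- expand_iri(o[o_iri], g$prefixes)
  dt[!is.na(dt)] <- expand_iri(dt[!is.na(dt)], g$prefixes)
  g$triples <- rbind(g$triples, data.frame(
    s = s, p = p, o = o, o_iri = o_iri, dt = dt, stringsAsFactors = FALSE
  ))
  g
}

rdf_merge <- function(a, b) {
  stopifnot(inherits(a, "rdf_graph"), inherits(b, "rdf_graph"))
  pf <- c(a$prefixes, b$prefixes[setdiff(names(b$prefixes), names(a$prefixes))])
  g <- rdf_graph(pf)
  g$triples <- unique(rbind(a$triples, b$triples))
  g
}

#' Number of triples in a graph
#' @param g an `rdf_graph`.
#' @return integer count.
#' @export
rdf_size <- function(g) nrow(g$triples)

#' Match triples against a basic graph pattern
#'
#' `NULL` positions are wildcards. CURIEs in `s`, `p` and (for IRI objects)
#' `o` are expanded before matching.
#'
#' @param g an `rdf_graph`.
#' @param s,p,o constants or `NULL` wildcards.
#' @param o_iri restrict the object to IRIs (`TRUE`), literals (`FALSE`) or
#'   either (`NA`, default).
#' @return data frame of matching triple rows.
#' @export
rdf_match <- function(g, s = NULL, p = NULL, o = NULL, o_iri = NA) {
  tr <- g$triples
  keep <- rep(TRUE, nrow(tr))
  if (!is.null(s)) keep <- keep & tr$s %in% expand_iri(s, g$prefixes)
  if (!is.null(p)) keep <- keep & tr$p %in% expand_iri(p, g$prefixes)
  if (!is.null(o)) {
    oo <- if (isTRUE(o_iri) || (is.na(o_iri) && any(grepl(":", o)))) {
      # expansion is harmless for literals that contain no known prefix
      tryCatch(expand_iri(o, g$prefixes), error = function(e) o)
    } else o
    keep <- keep & (tr$o %in% oo | tr$o %in% o)
  }
  if (!is.na(o_iri)) keep <- keep & tr$o_iri == o_iri
  tr[keep, , drop = FALSE]
}

triple_key <- function(tr) {
  paste(tr$s, tr$p, tr$o, tr$o_iri, ifelse(is.na(tr$dt), "", tr$dt), sep = "\r")
}

#' Test two graphs for isomorphism
#'
#' No blank nodes are ever emitted, so isomorphism is set equality of the
#' expanded triples (prefix bindings are ignored).
#'
#' @param a,b `rdf_graph` objects.
#' @return logical.
#' @export
rdf_isomorphic <- function(a, b) {
  setequal(triple_key(a$triples), triple_key(b$triples))
}

#' @export
print.rdf_graph <- function(x, ...) {
  cat("<rdf_graph> ", rdf_size(x), " triples, ",
      length(x$prefixes), " prefixes\n", sep = "")
  invisible(x)
}

escape_ttl <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_ttl <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    chars <- strsplit(x[[i]], "", fixed = TRUE)[[1]]
    res <- character(0)
    j <- 1L
    while (j <= length(chars)) {
      if (chars[j] == "\\" && j < length(chars)) {
        nxt <- chars[j + 1L]
        res <- c(res, switch(nxt,
                             n = "\n", r = "\r", t = "\t",
                             `"` = "\"", `\\` = "\\", nxt))
        j <- j + 2L
      } else {
        res <- c(res, chars[j])
        j <- j + 1L
      }
    }
    out[i] <- paste(res, collapse = "")
  }
  out
}

term_ttl <- function(iri, prefixes) {
  cp <- compact_iri(iri, prefixes)
  ifelse(is.na(cp), paste0("<", iri, ">"), cp)
}

#' Serialize a graph as Turtle
#'
#' Emits a stable prefix block followed by subject-grouped predicate lists;
#' subjects, predicates and objects are sorted so serialisation is
#' deterministic.
#'
#' @param g an `rdf_graph`.
#' @param path optional file to write to.
#' @return the Turtle text, invisibly when `path` is given.
#' @export
serialize_turtle <- function(g, path = NULL) {
  stopifnot(inherits(g, "rdf_graph"))
  pf <- g$prefixes[order(names(g$prefixes))]
  lines <- paste0("@prefix ", names(pf), ": <", pf, "> .")
  tr <- unique(g$triples)
  if (nrow(tr)) {
    rdf_type <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
    tr <- tr[order(tr$s, tr$p != rdf_type, tr$p, tr$o), , drop = FALSE]
    obj <- ifelse(
      tr$o_iri,
      term_ttl(tr$o, pf),
      paste0("\"", escape_ttl(tr$o), "\"",
             ifelse(is.na(tr$dt), "", paste0("^^", term_ttl(ifelse(is.na(tr$dt), rdf_type, tr$dt), pf))))
    )
    for (subj in unique(tr$s)) {
      rows <- tr[tr$s == subj, , drop = FALSE]
      objs <- obj[tr$s == subj]
      lines <- c(lines, "", term_ttl(subj, pf))
      for (k in seq_len(nrow(rows))) {
        sep <- if (k == nrow(rows)) " ." else " ;"
        lines <- c(lines, paste0("    ", term_ttl(rows$p[k], pf), " ", objs[k], sep))
      }
    }
  }
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

ttl_tokenize <- function(text) {
  # tokenizer for the Turtle subset the serializer emits (plus 'a' and
  # comments); returns data.frame(type, value, line)
  n <- nchar(text)
  pos <- 1L
  line <- 1L
  types <- character(0); vals <- character(0); lns <- integer(0)
  push <- function(ty, v) {
    types[[length(types) + 1L]] <<- ty
    vals[[length(vals) + 1L]] <<- v
    lns[[length(lns) + 1L]] <<- line
  }
  while (pos <= n) {
    ch <- substr(text, pos, pos)
    if (ch == "\n") { line <- line + 1L; pos <- pos + 1L; next }
    if (grepl("^[ \t\r]$", ch)) { pos <- pos + 1L; next }
    if (ch == "#") {
      nl <- regexpr("\n", substring(text, pos), fixed = TRUE)
      pos <- if (nl > 0) pos + nl - 1L else n + 1L
      next
    }
    rest <- substring(text, pos)
    if (ch == "<") {
      m <- regmatches(rest, regexpr("^<[^<>\"{}|^`\\\\ ]*>", rest))
      if (!length(m)) stop_input("Turtle parse error at line ", line, ": malformed IRI")
      push("iri", substr(m, 2, nchar(m) - 1L)); pos <- pos + nchar(m); next
    }
    if (ch == "\"") {
      m <- regmatches(rest, regexpr('^"(\\\\.|[^"\\\\])*"', rest))
      if (!length(m)) stop_input("Turtle parse error at line ", line, ": unterminated string")
      push("string", unescape_ttl(substr(m, 2, nchar(m) - 1L)))
      pos <- pos + nchar(m)
      line <- line + lengths(regmatches(m, gregexpr("\n", m, fixed = TRUE)))
      next
    }
    if (startsWith(rest, "^^")) { push("dtmark", "^^"); pos <- pos + 2L; next }
    if (startsWith(rest, "@prefix")) { push("atprefix", "@prefix"); pos <- pos + 7L; next }
    if (ch %in% c(";", ",", ".")) { push(ch, ch); pos <- pos + 1L; next }
    m <- regmatches(rest, regexpr("^[A-Za-z0-9_.-]*:[A-Za-z0-9_.-]*", rest))
    if (length(m) && nchar(m)) { push("pname", m); pos <- pos + nchar(m); next }
    m <- regmatches(rest, regexpr("^[A-Za-z][A-Za-z0-9_-]*", rest))
    if (length(m) && m == "a") { push("a", "a"); pos <- pos + 1L; next }
    stop_input("Turtle parse error at line ", line, ": unexpected character '", ch, "'")
  }
  data.frame(type = types, value = vals, line = lns, stringsAsFactors = FALSE)
}

#' Parse Turtle text into a graph
#'
#' Supports the subset produced by [serialize_turtle()]: `@prefix`
#' declarations, IRIs, prefixed names, the `a` keyword, string literals with
#' optional `^^` datatypes, and `;`/`,` predicate-object lists. Errors name
#' the offending line.
#'
#' @param text Turtle source (single string or character vector of lines).
#' @return an `rdf_graph`.
#' @export
parse_turtle <- function(text) {
  text <- paste(text, collapse = "\n")
  tk <- ttl_tokenize(text)
  prefixes <- character(0)
  g <- NULL
  i <- 1L
  nt <- nrow(tk)
  fail <- function(i, msg) {
    ln <- if (i <= nt) tk$line[i] else if (nt) tk$line[nt] else 1L
    stop_input("Turtle parse error at line ", ln, ": ", msg)
  }
  resolve <- function(i) {
    # returns expanded IRI for an iri/pname/a token
    ty <- tk$type[i]
    if (ty == "iri") return(tk$value[i])
    if (ty == "a") return("http://www.w3.org/1999/02/22-rdf-syntax-ns#type")
    if (ty == "pname") {
      pfx <- sub(":.*$", "", tk$value[i])
      if (!pfx %in% names(prefixes)) fail(i, paste0("undeclared prefix '", pfx, "'"))
      return(paste0(prefixes[[pfx]], sub("^[^:]*:", "", tk$value[i])))
    }
    fail(i, "expected IRI or prefixed name")
  }
  triples <- list()
  while (i <= nt) {
    if (tk$type[i] == "atprefix") {
      if (i + 3L > nt || tk$type[i + 1L] != "pname" || tk$type[i + 2L] != "iri" ||
          tk$type[i + 3L] != ".") fail(i, "malformed @prefix declaration")
      prefixes[[sub(":$", "", tk$value[i + 1L])]] <- tk$value[i + 2L]
      i <- i + 4L
      next
    }
    subj <- resolve(i); i <- i + 1L
    repeat {
      if (i > nt) fail(i, "unexpected end of input in predicate list")
      pred <- resolve(i); i <- i + 1L
      repeat {
        if (i > nt) fail(i, "unexpected end of input in object list")
        if (tk$type[i] %in% c("iri", "pname", "a")) {
          triples[[length(triples) + 1L]] <-
            list(s = subj, p = pred, o = resolve(i), o_iri = TRUE, dt = NA_character_)
          i <- i + 1L
        } else if (tk$type[i] == "string") {
          val <- tk$value[i]; i <- i + 1L
          dt <- NA_character_
          if (i <= nt && tk$type[i] == "dtmark") {
            dt <- resolve(i + 1L)
            i <- i + 2L
          }
          triples[[length(triples) + 1L]] <-
            list(s = subj, p = pred, o = val, o_iri = FALSE, dt = dt)
        } else fail(i, "expected object term")
        if (i <= nt && tk$type[i] == ",") { i <- i + 1L; next }
        break
      }
      if (i <= nt && tk$type[i] == ";") {
        i <- i + 1L
        # tolerate trailing ';' before '.'
        if (i <= nt && tk$type[i] == ".") { i <- i + 1L; break }
        next
      }
      if (i <= nt && tk$type[i] == ".") { i <- i + 1L; break }
      fail(i, "expected ';', ',' or '.'")
    }
  }
  pf <- default_prefixes()
  extra <- prefixes[setdiff(names(prefixes), names(pf))]
  if (length(extra)) pf <- c(pf, unlist(extra))
  for (nm in intersect(names(prefixes), names(pf))) pf[[nm]] <- prefixes[[nm]]
  g <- rdf_graph(pf)
  if (length(triples)) {
    g$triples <- unique(data.frame(
      s = vapply(triples, `[[`, "", "s"),
      p = vapply(triples, `[[`, "", "p"),
      o = vapply(triples, `[[`, "", "o"),
      o_iri = vapply(triples, `[[`, TRUE, "o_iri"),
      dt = vapply(triples, `[[`, "", "dt"),
      stringsAsFactors = FALSE
    ))
  }
  g
}
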