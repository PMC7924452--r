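local_name <- function(iri) sub("^.*[#/]", "", iri)

# workflow node for a params entry: accepts a full IRI, a CURIE, or a
# version string resolved through dc:hasVersion on dul:Workflow nodes
resolve_workflow <- function(g, x) {
  if (is.null(x)) stop_input("competency question: missing workflow/version parameter")
  wfs <- rdf_match(g, p = "rdf:type", o = "dul:Workflow")$s
  if (grepl(":", x)) {
    iri <- tryCatch(expand_iri(x, g$prefixes), error = function(e) x)
    if (iri %in% wfs) return(iri)
  }
  ver <- rdf_match(g, p = "dc:hasVersion", o = x, o_iri = FALSE)
  hit <- intersect(ver$s, wfs)
  if (length(hit) == 1) return(hit)
  if (length(hit) > 1) stop_input("competency question: version '", x, "' is ambiguous")
  stop_input("competency question: unknown workflow or version '", x, "'")
}

steps_of_workflow <- function(g, wf) {
  sort(rdf_match(g, p = "p-plan:isStepOfPlan", o = wf)$s)
}

step_kind <- function(g, step) {
  ty <- rdf_match(g, s = step, p = "rdf:type")$o
  manual <- expand_iri("bpmn:ManualTask", g$prefixes) %in% ty
  script <- expand_iri("bpmn:ScriptTask", g$prefixes) %in% ty
  if (manual) "manual" else if (script) "script" else NA_character_
}

plan_of_step <- function(g, step) {
  p <- rdf_match(g, s = step, p = "dul:isDescribedBy")$o
  if (length(p)) p[1] else NA_character_
}

canon_rows <- function(df) {
  if (!nrow(df)) return(df)
  df <- df[do.call(order, as.list(df)), , drop = FALSE]
  rownames(df) <- NULL
  df
}

cq_result <- function(cq_id, df) {
  structure(list(cq_id = cq_id, columns = names(df), rows = canon_rows(df)),
            class = "cq_result")
}

#' @export
print.cq_result <- function(x, ...) {
  cat("<cq_result> CQ", x$cq_id, " (", nrow(x$rows), " rows)\n", sep = "")
  print(utils::head(x$rows, 20))
  invisible(x)
}

#' Order the steps of a workflow
#'
#' Starts from the workflow's `pwo:hasFirstStep` and orders its steps
#' topologically along transitive `dul:precedes`; steps of the workflow
#' that carry no ordering constraints follow in lexicographic order.
#'
#' @param g an `rdf_graph`.
#' @param workflow workflow IRI, CURIE or version string.
#' @return character vector of step IRIs in execution order.
#' @export
step_order <- function(g, workflow) {
  wf <- resolve_workflow(g, workflow)
  first <- rdf_match(g, s = wf, p = "pwo:hasFirstStep")$o
  if (!length(first)) stop_input("step_order: workflow has no first step")
  steps <- union(steps_of_workflow(g, wf), first)
  prec <- rdf_match(g, p = "dul:precedes")
  prec <- prec[prec$s %in% steps & prec$o %in% steps, , drop = FALSE]
  # Kahn's algorithm; the first step is seeded ahead, remaining ties break
  # lexicographically
  indeg <- stats::setNames(integer(length(steps)), steps)
  for (o in prec$o) indeg[[o]] <- indeg[[o]] + 1L
  out <- character(0)
  avail <- names(indeg)[indeg == 0]
  avail <- c(intersect(first, avail), sort(setdiff(avail, first)))
  while (length(avail)) {
    v <- avail[1]; avail <- avail[-1]
    out <- c(out, v)
    nxt <- prec$o[prec$s == v]
    for (o in nxt) {
      indeg[[o]] <- indeg[[o]] - 1L
      if (indeg[[o]] == 0L) avail <- sort(union(avail, o))
    }
  }
  if (length(out) != length(steps)) {
    stop_input("step_order: precedence relation contains a cycle")
  }
  out
}

#' Diff the instruction plans of two workflow versions
#'
#' An instruction is "used" by a version when it describes one of the
#' version's steps. `changed` are the new version's plans that
#' `prov:wasRevisionOf`-link to plans of the old version; `removed` are old
#' plans neither reused nor revised; `added` are new plans neither reused
#' nor revising.
#'
#' @param g an `rdf_graph`.
#' @param v_old,v_new workflow IRIs, CURIEs or version strings.
#' @return object of class `version_diff`: list with `removed`, `changed`,
#'   `added` character vectors (pairwise disjoint).
#' @export
diff_versions <- function(g, v_old, v_new) {
  wf_old <- resolve_workflow(g, v_old)
  wf_new <- resolve_workflow(g, v_new)
  plans_old <- unique(stats::na.omit(vapply(steps_of_workflow(g, wf_old),
                                            function(s) plan_of_step(g, s), "")))
  plans_new <- unique(stats::na.omit(vapply(steps_of_workflow(g, wf_new),
                                            function(s) plan_of_step(g, s), "")))
  rev <- rdf_match(g, p = "prov:wasRevisionOf")
  rev <- rev[rev$s %in% plans_new & rev$o %in% plans_old, , drop = FALSE]
  changed_new <- unique(rev$s)
  revised_old <- unique(rev$o)
  reused <- intersect(plans_old, plans_new)
  removed <- setdiff(plans_old, union(reused, revised_old))
  added <- setdiff(plans_new, union(reused, changed_new))
  out <- list(removed = sort(removed), changed = sort(changed_new),
              added = sort(added))
  class(out) <- "version_diff"
  out
}

#' @export
print.version_diff <- function(x, ...) {
  cat("<version_diff> removed:", length(x$removed),
      " changed:", length(x$changed), " added:", length(x$added), "\n")
  invisible(x)
}

CQ_IDS <- c("1.1", "1.2", "1.3", "1.4", "2.1", "2.2", "2.3", "2.4",
            "3.1", "3.2", "3.3", "3.4", "3.5")

# distributions manually handled within a workflow: distribution rows bound
# through prov:qualifiedUsage of plans describing its manual steps
manual_distributions <- function(g, wf) {
  steps <- steps_of_workflow(g, wf)
  rows <- list()
  for (s in steps) {
    if (!identical(step_kind(g, s), "manual")) next
    plan <- plan_of_step(g, s)
    if (is.na(plan)) next
    for (u in rdf_match(g, s = plan, p = "prov:qualifiedUsage")$o) {
      ents <- rdf_match(g, s = u, p = "prov:entity")$o
      dists <- ents[vapply(ents, function(e) {
        expand_iri("dcat:Distribution", g$prefixes) %in%
          rdf_match(g, s = e, p = "rdf:type")$o
      }, TRUE)]
      for (d in dists) {
        url <- rdf_match(g, s = d, p = "dcat:downloadURL")$o
        mt <- rdf_match(g, s = d, p = "dcat:mediaType")$o
        rows[[length(rows) + 1L]] <- data.frame(
          step = s, distribution = d,
          download_url = if (length(url)) url[1] else NA_character_,
          media_type = if (length(mt)) mt[1] else NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(step = character(), distribution = character(),
                      download_url = character(), media_type = character(),
                      stringsAsFactors = FALSE))
  }
  unique(do.call(rbind, rows))
}

# dataset distributions used by a version (any step, manual or scripted)
version_distributions <- function(g, wf) {
  steps <- steps_of_workflow(g, wf)
  out <- character(0)
  for (s in steps) {
    plan <- plan_of_step(g, s)
    if (is.na(plan)) next
    for (u in rdf_match(g, s = plan, p = "prov:qualifiedUsage")$o) {
      ents <- rdf_match(g, s = u, p = "prov:entity")$o
      out <- union(out, ents[vapply(ents, function(e) {
        expand_iri("dcat:Distribution", g$prefixes) %in%
          rdf_match(g, s = e, p = "rdf:type")$o
      }, TRUE)])
    }
  }
  sort(out)
}

#' Answer a competency question over a provenance graph
#'
#' Native triple-pattern implementations of the thirteen competency
#' questions; the equivalent SPARQL 1.1 queries are shipped under
#' `system.file("sparql", package = "repurpose")` for use against external
#' stores. Row sets are canonicalised (sorted) so repeated evaluation is
#' deterministic.
#'
#' CQ1.1 steps of a workflow with manual/script typing and their plans;
#' CQ1.2 agent/role associations of manual-step instructions;
#' CQ1.3 manually handled dataset distributions with URL and media type;
#' CQ1.4 manual-step operation types with input/output variables;
#' CQ2.1/2.2 ordered (main) steps via first-step + transitive precedes;
#' CQ2.3 plan-describes-plan abstraction links;
#' CQ2.4 associations (agent, role) over instantiation links;
#' CQ3.1 workflow versions with their provenance;
#' CQ3.2 instructions removed/changed/added between two versions;
#' CQ3.3 instructions automatized (manual to script) between versions;
#' CQ3.4 dataset distributions removed/changed/added between versions;
#' CQ3.5 executions with their workflow version and generated evaluations.
#'
#' @param g an `rdf_graph`.
#' @param cq_id one of `"1.1"`..`"3.5"`.
#' @param params list; `workflow` for CQ1.x/2.x, `v_old` and `v_new` for
#'   CQ3.2-3.4 (all accept IRIs or version strings).
#' @return a `cq_result` (columns + canonicalised binding rows).
#' @export
answer_cq <- function(g, cq_id, params = list()) {
  cq_id <- as.character(cq_id)
  if (!cq_id %in% CQ_IDS) stop_input("answer_cq: unknown competency question '", cq_id, "'")
  empty <- function(...) {
    nm <- c(...)
    stats::setNames(data.frame(matrix(character(0), 0, length(nm)),
                               stringsAsFactors = FALSE), nm)
  }
  wf_param <- function() resolve_workflow(g, params$workflow %||% params$version)

  if (cq_id == "1.1") {
    if (!rdf_size(g)) return(cq_result(cq_id, empty("step", "kind", "plan")))
    wf <- wf_param()
    steps <- steps_of_workflow(g, wf)
    df <- data.frame(
      step = steps,
      kind = vapply(steps, function(s) step_kind(g, s), ""),
      plan = vapply(steps, function(s) plan_of_step(g, s), ""),
      stringsAsFactors = FALSE)
    df <- df[!is.na(df$kind), , drop = FALSE]
    return(cq_result(cq_id, df))
  }
  if (cq_id == "1.2") {
    if (!rdf_size(g)) return(cq_result(cq_id, empty("step", "agent", "role")))
    wf <- wf_param()
    steps <- steps_of_workflow(g, wf)
    rows <- list()
    assoc <- rdf_match(g, p = "rdf:type", o = "prov:Association")$s
    for (s in steps) {
      if (!identical(step_kind(g, s), "manual")) next
      plan <- plan_of_step(g, s)
      for (a in assoc) {
        if (!plan %in% rdf_match(g, s = a, p = "prov:hadPlan")$o) next
        ag <- rdf_match(g, s = a, p = "prov:agent")$o
        ro <- rdf_match(g, s = a, p = "prov:hadRole")$o
        if (length(ag) && length(ro)) {
          rows[[length(rows) + 1L]] <- expand.grid(
            step = s, agent = ag, role = ro, stringsAsFactors = FALSE)
        }
      }
    }
    df <- if (length(rows)) unique(do.call(rbind, rows)) else empty("step", "agent", "role")
    return(cq_result(cq_id, df))
  }
  if (cq_id == "1.3") {
    if (!rdf_size(g)) {
      return(cq_result(cq_id, empty("step", "distribution", "download_url", "media_type")))
    }
    return(cq_result(cq_id, manual_distributions(g, wf_param())))
  }
  if (cq_id == "1.4") {
    if (!rdf_size(g)) {
      return(cq_result(cq_id, empty("step", "operation", "direction", "variable")))
    }
    wf <- wf_param()
    rows <- list()
    for (s in steps_of_workflow(g, wf)) {
      if (!identical(step_kind(g, s), "manual")) next
      ty <- rdf_match(g, s = s, p = "rdf:type")$o
      ops <- ty[startsWith(ty, g$prefixes[["edam"]])]
      op <- if (length(ops)) ops[1] else NA_character_
      iv <- rdf_match(g, s = s, p = "p-plan:hasInputVar")$o
      ov <- rdf_match(g, s = s, p = "p-plan:hasOutputVar")$o
      io <- data.frame(direction = c(rep("input", length(iv)),
                                     rep("output", length(ov))),
                       variable = c(iv, ov), stringsAsFactors = FALSE)
      if (!nrow(io)) io <- data.frame(direction = NA_character_,
                                      variable = NA_character_,
                                      stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(step = s, operation = op, io,
                                              stringsAsFactors = FALSE)
    }
    df <- if (length(rows)) do.call(rbind, rows) else
      empty("step", "operation", "direction", "variable")
    return(cq_result(cq_id, df))
  }
  if (cq_id %in% c("2.1", "2.2")) {
    if (!rdf_size(g)) return(cq_result(cq_id, empty("position", "step", "plan")))
    wf <- wf_param()
    ord <- step_order(g, wf)
    if (cq_id == "2.1") {
      # main steps: the chain reachable from the first step along precedes
      first <- rdf_match(g, s = wf, p = "pwo:hasFirstStep")$o[1]
      chain <- first
      repeat {
        nxt <- rdf_match(g, s = chain[length(chain)], p = "dul:precedes")$o
        nxt <- setdiff(nxt, chain)
        if (!length(nxt)) break
        chain <- c(chain, nxt[1])
      }
      ord <- chain
    }
    df <- data.frame(position = seq_along(ord), step = ord,
                     plan = vapply(ord, function(s) plan_of_step(g, s), ""),
                     stringsAsFactors = FALSE)
    res <- structure(list(cq_id = cq_id, columns = names(df), rows = df),
                     class = "cq_result")  # execution order, not sorted
    return(res)
  }
  if (cq_id == "2.3") {
    plans <- rdf_match(g, p = "rdf:type", o = "p-plan:Plan")$s
    db <- rdf_match(g, p = "dul:isDescribedBy")
    db <- db[db$s %in% plans & db$o %in% plans, , drop = FALSE]
    df <- data.frame(plan = db$s, described_by = db$o, stringsAsFactors = FALSE)
    return(cq_result(cq_id, unique(df)))
  }
  if (cq_id == "2.4") {
    plans <- rdf_match(g, p = "rdf:type", o = "p-plan:Plan")$s
    db <- rdf_match(g, p = "dul:isDescribedBy")
    db <- db[db$s %in% plans & db$o %in% plans, , drop = FALSE]
    inst_plans <- unique(c(db$s, db$o))
    rows <- list()
    for (a in rdf_match(g, p = "rdf:type", o = "prov:Association")$s) {
      had <- intersect(rdf_match(g, s = a, p = "prov:hadPlan")$o, inst_plans)
      if (!length(had)) next
      ag <- rdf_match(g, s = a, p = "prov:agent")$o
      ro <- rdf_match(g, s = a, p = "prov:hadRole")$o
      for (p in had) {
        rows[[length(rows) + 1L]] <- expand.grid(
          plan = p, agent = ag, role = ro, stringsAsFactors = FALSE)
      }
    }
    df <- if (length(rows)) unique(do.call(rbind, rows)) else
      empty("plan", "agent", "role")
    return(cq_result(cq_id, df))
  }
  if (cq_id == "3.1") {
    wfs <- rdf_match(g, p = "rdf:type", o = "dul:Workflow")$s
    one <- function(s, p) {
      v <- rdf_match(g, s = s, p = p)$o
      if (length(v)) v[1] else NA_character_
    }
    df <- data.frame(
      workflow = wfs,
      version = vapply(wfs, function(s) one(s, "dc:hasVersion"), ""),
      created = vapply(wfs, function(s) one(s, "dc:created"), ""),
      modified = vapply(wfs, function(s) one(s, "dc:modified"), ""),
      creator = vapply(wfs, function(s) one(s, "dc:creator"), ""),
      attributed_to = vapply(wfs, function(s) one(s, "prov:wasAttributedTo"), ""),
      revision_of = vapply(wfs, function(s) one(s, "prov:wasRevisionOf"), ""),
      stringsAsFactors = FALSE)
    return(cq_result(cq_id, df))
  }
  if (cq_id == "3.2") {
    d <- diff_versions(g, params$v_old, params$v_new)
    df <- rbind(
      data.frame(status = "removed", plan = d$removed, stringsAsFactors = FALSE),
      data.frame(status = "changed", plan = d$changed, stringsAsFactors = FALSE),
      data.frame(status = "added", plan = d$added, stringsAsFactors = FALSE))
    return(cq_result(cq_id, df))
  }
  if (cq_id == "3.3") {
    wf_old <- resolve_workflow(g, params$v_old)
    wf_new <- resolve_workflow(g, params$v_new)
    steps_old <- steps_of_workflow(g, wf_old)
    steps_new <- steps_of_workflow(g, wf_new)
    plan_step_old <- stats::setNames(
      steps_old, vapply(steps_old, function(s) plan_of_step(g, s), ""))
    rows <- list()
    for (s in steps_new) {
      if (!identical(step_kind(g, s), "script")) next
      plan <- plan_of_step(g, s)
      for (o in rdf_match(g, s = plan, p = "prov:wasRevisionOf")$o) {
        old_step <- plan_step_old[[o]]
        if (!is.null(old_step) && identical(step_kind(g, old_step), "manual")) {
          rows[[length(rows) + 1L]] <- data.frame(
            new_plan = plan, old_plan = o, new_step = s, old_step = old_step,
            stringsAsFactors = FALSE)
        }
      }
    }
    df <- if (length(rows)) unique(do.call(rbind, rows)) else
      empty("new_plan", "old_plan", "new_step", "old_step")
    return(cq_result(cq_id, df))
  }
  if (cq_id == "3.4") {
    wf_old <- resolve_workflow(g, params$v_old)
    wf_new <- resolve_workflow(g, params$v_new)
    d_old <- version_distributions(g, wf_old)
    d_new <- version_distributions(g, wf_new)
    df <- rbind(
      data.frame(status = "removed", distribution = setdiff(d_old, d_new),
                 stringsAsFactors = FALSE),
      data.frame(status = "added", distribution = setdiff(d_new, d_old),
                 stringsAsFactors = FALSE))
    return(cq_result(cq_id, df))
  }
  # CQ3.5
  acts <- rdf_match(g, p = "rdf:type", o = "p-plan:Activity")$s
  rows <- list()
  for (a in acts) {
    step <- rdf_match(g, s = a, p = "p-plan:correspondsToStep")$o
    step <- if (length(step)) step[1] else NA_character_
    wf <- if (!is.na(step)) {
      w <- rdf_match(g, s = step, p = "p-plan:isStepOfPlan")$o
      if (length(w)) w[1] else NA_character_
    } else NA_character_
    ver <- if (!is.na(wf)) {
      v <- rdf_match(g, s = wf, p = "dc:hasVersion")$o
      if (length(v)) v[1] else NA_character_
    } else NA_character_
    gen <- rdf_match(g, s = a, p = "prov:generated")$o
    if (!length(gen)) {
      rows[[length(rows) + 1L]] <- data.frame(
        activity = a, step = step, workflow = wf, version = ver,
        artifact = NA_character_, measure = NA_character_,
        value = NA_character_, stringsAsFactors = FALSE)
      next
    }
    for (art in gen) {
      ms <- rdf_match(g, s = art, p = "mls:specifiedBy")$o
      val <- rdf_match(g, s = art, p = "dc:description", o_iri = FALSE)$o
      rows[[length(rows) + 1L]] <- data.frame(
        activity = a, step = step, workflow = wf, version = ver,
        artifact = art,
        measure = if (length(ms)) ms[1] else NA_character_,
        value = if (length(val)) val[1] else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    empty("activity", "step", "workflow", "version", "artifact", "measure", "value")
  cq_result("3.5", df)
}
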