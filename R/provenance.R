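#' Declarative workflow step
#'
#' A step is a lightweight ordering object; the instruction it points to is
#' a separate plan (`dul:isDescribedBy`), so instructions can be reused and
#' versioned independently of step order.
#'
#' @param id step identifier (local name).
#' @param label human-readable label.
#' @param kind `"manual"` (bpmn:ManualTask) or `"script"` (bpmn:ScriptTask).
#' @param operation EDAM operation class for the step (CURIE, e.g.
#'   `"edam:operation_2409"` for data handling), or `NA`.
#' @param instruction instruction text of the step's plan.
#' @param language instruction language label (e.g. `"English"`,
#'   `"Python 3.5"`).
#' @param inputs,outputs variable ids consumed/produced.
#' @param datasets named character vector binding variable ids to dataset
#'   distribution ids (names = variable id, values = distribution id).
#' @param described_by optional id of a higher-level plan this step's plan
#'   instantiates (abstraction link).
#' @param agents named character vector of agent roles (names = agent id,
#'   values = role label, e.g. `c(remzi = "Developer")`).
#' @param revises optional id of the step (in the prior workflow version)
#'   whose instruction this step's plan revises; drives the
#'   `prov:wasRevisionOf` links emitted by [link_revision()].
#' @return object of class `step_spec`.
#' @export
step_spec <- function(id, label = id, kind = c("manual", "script"),
                      operation = NA_character_, instruction = label,
                      language = "English", inputs = character(0),
                      outputs = character(0), datasets = character(0),
                      described_by = NA_character_, agents = character(0),
                      revises = NA_character_) {
  kind <- match.arg(kind)
  structure(list(id = id, label = label, kind = kind, operation = operation,
                 instruction = instruction, language = language,
                 inputs = inputs, outputs = outputs, datasets = datasets,
                 described_by = described_by, agents = agents,
                 revises = revises),
            class = "step_spec")
}

#' Dataset distribution descriptor
#'
#' @param id distribution identifier (local name).
#' @param label human-readable label.
#' @param download_url URL the distribution can be fetched from (required).
#' @param media_type media-type/format identifier (local name or CURIE).
#' @return object of class `dataset_distribution`.
#' @export
dataset_distribution <- function(id, label = id, download_url, media_type = NA_character_) {
  if (missing(download_url) || !nzchar(download_url)) {
    stop_input("dataset_distribution: download_url is required")
  }
  structure(list(id = id, label = label, download_url = download_url,
                 media_type = media_type),
            class = "dataset_distribution")
}

#' Prospective workflow description
#'
#' An ordered plan of steps with version metadata. Steps execute in list
#' order (each step `dul:precedes` the next); the first step is flagged with
#' `pwo:hasFirstStep`.
#'
#' @param id workflow identifier (local name).
#' @param version version string (e.g. `"0.1"`).
#' @param label human-readable label.
#' @param created,modified ISO dates.
#' @param creator agent identifier (local name).
#' @param steps list of [step_spec()] objects, in execution order.
#' @param distributions list of [dataset_distribution()] objects referenced
#'   by the steps' dataset bindings.
#' @param prior_version optional id of the workflow this one revises.
#' @return object of class `workflow_spec`.
#' @export
workflow_spec <- function(id, version, label = id, created = format(Sys.Date()),
                          modified = created, creator = "Agent_author",
                          steps = list(), distributions = list(),
                          prior_version = NA_character_) {
  if (!length(steps)) stop_input("workflow_spec: at least one step required")
  ids <- vapply(steps, `[[`, "", "id")
  if (anyDuplicated(ids)) stop_input("workflow_spec: duplicate step ids")
  structure(list(id = id, version = version, label = label, created = created,
                 modified = modified, creator = creator, steps = steps,
                 distributions = distributions, prior_version = prior_version),
            class = "workflow_spec")
}

#' Record of one workflow execution
#'
#' @param run_id execution identifier (e.g. a UNIX timestamp string).
#' @param activities data frame with columns `step_id`, `start`, `end`
#'   (ISO-8601 timestamps with millisecond precision).
#' @param metrics named numeric vector of evaluation measures generated by
#'   the run (e.g. `c(Accuracy = 0.83, RocAuc = 0.87)`).
#' @param agent executing software agent (local name).
#' @param agent_version software version string.
#' @param generated_at ISO-8601 timestamp of artifact generation.
#' @return object of class `run_record`.
#' @export
run_record <- function(run_id, activities, metrics = numeric(0),
                       agent = "Agent_workflow_engine", agent_version = "1.0",
                       generated_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3")) {
  stopifnot(is.data.frame(activities), all(c("step_id") %in% names(activities)))
  structure(list(run_id = run_id, activities = activities, metrics = metrics,
                 agent = agent, agent_version = agent_version,
                 generated_at = generated_at),
            class = "run_record")
}

op_iri <- function(x) paste0("opredict:", x)

task_class <- function(kind) {
  if (kind == "manual") "bpmn:ManualTask" else "bpmn:ScriptTask"
}

lang_node <- function(language) {
  paste0("opredict:LinguisticSystem_", gsub("[^A-Za-z0-9]+", "_", language))
}

#' Emit the prospective provenance graph of a workflow
#'
#' The workflow is a `dul:Workflow` and `p-plan:Plan` carrying version,
#' dates and creator; each step is typed `p-plan:Step` plus its
#' manual/script task class and EDAM operation, chained with `dul:precedes`
#' from the `pwo:hasFirstStep`; every step `dul:isDescribedBy` its own
#' instruction plan; variables hang off `p-plan:hasInputVar` /
#' `p-plan:hasOutputVar`; dataset bindings are reified `prov:Usage` nodes
#' reached via `prov:qualifiedUsage`; agent roles are reified
#' `prov:Association` nodes with `prov:agent`, `prov:hadRole` and
#' `prov:hadPlan`.
#'
#' @param spec a [workflow_spec()].
#' @param base IRI base for minted namespaces.
#' @return an `rdf_graph`.
#' @export
describe_workflow <- function(spec, base = "https://w3id.org/fair/plex") {
  stopifnot(inherits(spec, "workflow_spec"))
  g <- rdf_graph(default_prefixes(base))
  wf <- op_iri(spec$id)
  g <- rdf_add(g, wf, "rdf:type", c("p-plan:Plan", "dul:Workflow"))
  g <- rdf_add(g, wf, "rdfs:label", spec$label, o_iri = FALSE)
  g <- rdf_add(g, wf, "dc:description", spec$label, o_iri = FALSE)
  g <- rdf_add(g, wf, "dc:hasVersion", spec$version, o_iri = FALSE)
  g <- rdf_add(g, wf, "dc:created", spec$created, o_iri = FALSE)
  g <- rdf_add(g, wf, "dc:modified", spec$modified, o_iri = FALSE)
  g <- rdf_add(g, wf, "dc:creator", op_iri(spec$creator))
  g <- rdf_add(g, wf, "prov:wasAttributedTo", op_iri(spec$creator))
  g <- rdf_add(g, op_iri(spec$creator), "rdf:type", "prov:Agent")
  if (!is.na(spec$prior_version)) {
    g <- rdf_add(g, wf, "prov:wasRevisionOf", op_iri(spec$prior_version))
  }
  step_ids <- vapply(spec$steps, `[[`, "", "id")
  g <- rdf_add(g, wf, "pwo:hasFirstStep", op_iri(step_ids[1]))
  for (i in seq_along(spec$steps)) {
    st <- spec$steps[[i]]
    s <- op_iri(st$id)
    plan <- op_iri(paste0("Plan_", st$id))
    g <- rdf_add(g, s, "rdf:type", c("p-plan:Step", task_class(st$kind)))
    if (!is.na(st$operation)) g <- rdf_add(g, s, "rdf:type", st$operation)
    g <- rdf_add(g, s, "rdfs:label", st$label, o_iri = FALSE)
    g <- rdf_add(g, s, "p-plan:isStepOfPlan", wf)
    g <- rdf_add(g, s, "dul:isDescribedBy", plan)
    if (i < length(spec$steps)) {
      g <- rdf_add(g, s, "dul:precedes", op_iri(step_ids[i + 1]))
    }
    g <- rdf_add(g, plan, "rdf:type", "p-plan:Plan")
    g <- rdf_add(g, plan, "dc:description", st$instruction, o_iri = FALSE)
    g <- rdf_add(g, plan, "rdfs:label", st$label, o_iri = FALSE)
    g <- rdf_add(g, plan, "dc:language", lang_node(st$language))
    g <- rdf_add(g, lang_node(st$language), "rdf:type", "dc:LinguisticSystem")
    if (!is.na(st$described_by)) {
      g <- rdf_add(g, plan, "dul:isDescribedBy", op_iri(st$described_by))
      g <- rdf_add(g, op_iri(st$described_by), "rdf:type", "p-plan:Plan")
    }
    for (v in st$inputs) {
      g <- rdf_add(g, s, "p-plan:hasInputVar", op_iri(v))
      g <- rdf_add(g, op_iri(v), "rdf:type", "p-plan:Variable")
    }
    for (v in st$outputs) {
      g <- rdf_add(g, s, "p-plan:hasOutputVar", op_iri(v))
      g <- rdf_add(g, op_iri(v), "rdf:type", "p-plan:Variable")
    }
    for (v in names(st$datasets)) {
      usage <- op_iri(paste0("Usage_", st$id, "_", v))
      g <- rdf_add(g, plan, "prov:qualifiedUsage", usage)
      g <- rdf_add(g, usage, "rdf:type", "prov:Usage")
      g <- rdf_add(g, usage, "rdfs:label",
                   paste("Link variable", v, "to distribution"), o_iri = FALSE)
      g <- rdf_add(g, usage, "prov:entity", op_iri(st$datasets[[v]]))
      g <- rdf_add(g, usage, "prov:entity", op_iri(v))
    }
    for (a in names(st$agents)) {
      assoc <- op_iri(paste0("Association_", a, "_", st$agents[[a]], "_", st$id))
      g <- rdf_add(g, assoc, "rdf:type", "prov:Association")
      g <- rdf_add(g, assoc, "prov:agent", op_iri(a))
      g <- rdf_add(g, assoc, "prov:hadRole", op_iri(paste0("Role_", st$agents[[a]])))
      g <- rdf_add(g, op_iri(paste0("Role_", st$agents[[a]])), "rdf:type", "prov:Role")
      g <- rdf_add(g, assoc, "prov:hadPlan", plan)
      g <- rdf_add(g, op_iri(a), "rdf:type", "prov:Agent")
    }
  }
  for (d in spec$distributions) {
    dn <- op_iri(d$id)
    g <- rdf_add(g, dn, "rdf:type", "dcat:Distribution")
    g <- rdf_add(g, dn, "rdfs:label", d$label, o_iri = FALSE)
    g <- rdf_add(g, dn, "dcat:downloadURL", d$download_url, o_iri = FALSE)
    if (!is.na(d$media_type)) {
      g <- rdf_add(g, dn, "dcat:mediaType", op_iri(d$media_type))
    }
  }
  g
}

#' Emit the retrospective provenance graph of one execution
#'
#' One `p-plan:Activity` per executed step, linked by
#' `p-plan:correspondsToStep`; every evaluation measure becomes an
#' `mls:ModelEvaluation` artifact (also `opmw:WorkflowExecutionArtifact`)
#' generated by the activity, holding its value as `dc:description` and a
#' `prov:qualifiedGeneration` node carrying the timestamp.
#'
#' @param spec the [workflow_spec()] that was executed.
#' @param run a [run_record()].
#' @param base IRI base for minted namespaces.
#' @return an `rdf_graph`.
#' @export
record_execution <- function(spec, run, base = "https://w3id.org/fair/plex") {
  stopifnot(inherits(spec, "workflow_spec"), inherits(run, "run_record"))
  step_ids <- vapply(spec$steps, `[[`, "", "id")
  unknown <- setdiff(run$activities$step_id, step_ids)
  if (length(unknown)) {
    stop_input("record_execution: activities reference unknown step(s): ",
               paste(unknown, collapse = ", "))
  }
  g <- rdf_graph(default_prefixes(base))
  if (!nrow(run$activities)) return(g)
  gen <- op_iri(paste0("Generation_Execution_", run$run_id))
  agent <- op_iri(run$agent)
  g <- rdf_add(g, agent, "rdf:type", "prov:SoftwareAgent")
  g <- rdf_add(g, agent, "dc:hasVersion", run$agent_version, o_iri = FALSE)
  last_step <- run$activities$step_id[nrow(run$activities)]
  for (i in seq_len(nrow(run$activities))) {
    a <- run$activities[i, ]
    act <- op_iri(paste0("Activity_", a$step_id, "_Execution_", run$run_id))
    g <- rdf_add(g, act, "rdf:type", "p-plan:Activity")
    g <- rdf_add(g, act, "p-plan:correspondsToStep", op_iri(a$step_id))
    g <- rdf_add(g, act, "prov:wasAssociatedWith", agent)
    if (!is.null(a$start) && !is.na(a$start)) {
      g <- rdf_add(g, act, "prov:startedAtTime", a$start, o_iri = FALSE, dt = "xsd:dateTime")
    }
    if (!is.null(a$end) && !is.na(a$end)) {
      g <- rdf_add(g, act, "prov:endedAtTime", a$end, o_iri = FALSE, dt = "xsd:dateTime")
    }
    if (a$step_id == last_step && length(run$metrics)) {
      for (mname in names(run$metrics)) {
        art <- op_iri(paste0("ModelEvaluation_", mname, "_Execution_", run$run_id))
        g <- rdf_add(g, act, "prov:generated", art)
        g <- rdf_add(g, art, "rdf:type", c("mls:ModelEvaluation",
                                           "opmw:WorkflowExecutionArtifact"))
        g <- rdf_add(g, art, "dc:description",
                     format(run$metrics[[mname]], digits = 6, scientific = FALSE),
                     o_iri = FALSE)
        g <- rdf_add(g, art, "mls:specifiedBy",
                     op_iri(paste0("EvaluationMeasure_", mname)))
        g <- rdf_add(g, op_iri(paste0("EvaluationMeasure_", mname)),
                     "rdf:type", "mls:EvaluationMeasure")
        g <- rdf_add(g, art, "prov:qualifiedGeneration", gen)
      }
      g <- rdf_add(g, gen, "rdf:type", "prov:Generation")
      g <- rdf_add(g, gen, "prov:atTime", run$generated_at,
                   o_iri = FALSE, dt = "xsd:dateTime")
    }
  }
  g
}

#' Emit version links between two workflow versions
#'
#' Both workflow nodes carry their `dc:hasVersion` literal and the new
#' version links to the old with `prov:wasRevisionOf`. Instruction plans of
#' steps sharing an id across the versions (but differing in kind,
#' instruction text or language) also carry pairwise revision links.
#'
#' @param new,old [workflow_spec()] objects with distinct versions.
#' @param base IRI base for minted namespaces.
#' @return an `rdf_graph`.
#' @export
link_revision <- function(new, old, base = "https://w3id.org/fair/plex") {
  stopifnot(inherits(new, "workflow_spec"), inherits(old, "workflow_spec"))
  if (identical(new$id, old$id) || identical(new$version, old$version)) {
    stop_input("link_revision: a workflow version cannot revise itself")
  }
  g <- rdf_graph(default_prefixes(base))
  g <- rdf_add(g, op_iri(new$id), "dc:hasVersion", new$version, o_iri = FALSE)
  g <- rdf_add(g, op_iri(old$id), "dc:hasVersion", old$version, o_iri = FALSE)
  g <- rdf_add(g, op_iri(new$id), "prov:wasRevisionOf", op_iri(old$id))
  old_steps <- stats::setNames(old$steps, vapply(old$steps, `[[`, "", "id"))
  for (st in new$steps) {
    if (is.na(st$revises) || is.null(old_steps[[st$revises]])) next
    g <- rdf_add(g, op_iri(paste0("Plan_", st$id)), "prov:wasRevisionOf",
                 op_iri(paste0("Plan_", st$revises)))
  }
  g
}
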