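test_that("CQ answers on the worked-example fixture match the printed values", {
  fx <- build_paper_fixture()
  r11 <- answer_cq(fx, "1.1", list(workflow = "0.1"))
  dl <- r11$rows[repurpose:::local_name(r11$rows$step) == "Step_Download_Drugbank_dataset", ]
  expect_equal(nrow(dl), 1)
  expect_equal(dl$kind, "manual")
  expect_equal(repurpose:::local_name(dl$plan), "Plan_Download_Drugbank_dataset")

  r13 <- answer_cq(fx, "1.3", list(workflow = "0.1"))
  expect_true("http://download.bio2rdf.org/files/release/4/drugbank/drugbank.nq.gz"
              %in% r13$rows$download_url)

  r35 <- answer_cq(fx, "3.5")
  acc <- r35$rows[grepl("ModelEvaluation_Accuracy_Execution_1546302862",
                        r35$rows$artifact), ]
  expect_equal(acc$value, "0.833336")
  expect_equal(acc$version, "0.1")
})

test_that("every competency question returns zero rows on an empty graph", {
  g <- rdf_graph()
  for (id in c("1.1", "1.2", "1.3", "1.4", "3.5")) {
    r <- answer_cq(g, id, list(workflow = "0.1"))
    expect_equal(nrow(r$rows), 0, label = paste("CQ", id))
  }
  expect_equal(nrow(answer_cq(g, "2.3")$rows), 0)
  expect_equal(nrow(answer_cq(g, "2.4")$rows), 0)
  expect_equal(nrow(answer_cq(g, "3.1")$rows), 0)
  expect_error(answer_cq(g, "9.9"), "unknown competency question")
  expect_error(answer_cq(build_paper_fixture(), "1.1"), "missing workflow")
})

test_that("repeated evaluation yields identical canonicalized results", {
  fx <- build_paper_fixture()
  for (id in c("1.1", "1.2", "1.3", "2.3", "2.4", "3.1", "3.5")) {
    a <- answer_cq(fx, id, list(workflow = "0.1"))
    b <- answer_cq(fx, id, list(workflow = "0.1"))
    expect_identical(a$rows, b$rows, label = paste("CQ", id))
  }
})

test_that("step ordering follows first-step and precedes, and rejects cycles", {
  spec <- workflow_spec(id = "Plan_Chain", version = "0.9",
                        steps = list(step_spec("Step_a", kind = "script"),
                                     step_spec("Step_b", kind = "script"),
                                     step_spec("Step_c", kind = "script")))
  g <- describe_workflow(spec)
  expect_identical(repurpose:::local_name(step_order(g, "0.9")),
                   c("Step_a", "Step_b", "Step_c"))

  # fixture: download precedes save
  fx <- build_paper_fixture()
  ord <- repurpose:::local_name(step_order(fx, "0.1"))
  expect_lt(which(ord == "Step_Download_Drugbank_dataset"),
            which(ord == "Step_Save_Drugbank_dataset"))

  cyc <- rdf_add(g, "opredict:Step_c", "dul:precedes", "opredict:Step_a")
  expect_error(step_order(cyc, "0.9"), "cycle")
})

test_that("step ordering is a valid topological sort of random precedence DAGs", {
  set.seed(61)
  for (k in 1:10) {
    n <- sample(4:8, 1)
    ids <- sprintf("Step_r%02d", seq_len(n))
    g <- rdf_graph()
    g <- rdf_add(g, "opredict:Plan_RandDag", "rdf:type", c("p-plan:Plan", "dul:Workflow"))
    g <- rdf_add(g, "opredict:Plan_RandDag", "dc:hasVersion", "1.0", o_iri = FALSE)
    g <- rdf_add(g, "opredict:Plan_RandDag", "pwo:hasFirstStep", paste0("opredict:", ids[1]))
    g <- rdf_add(g, paste0("opredict:", ids), "rdf:type", "p-plan:Step")
    g <- rdf_add(g, paste0("opredict:", ids), "p-plan:isStepOfPlan", "opredict:Plan_RandDag")
    edges <- data.frame(from = integer(0), to = integer(0))
    for (j in 2:n) {
      # edges only forward in index order: guaranteed acyclic
      src <- sample(seq_len(j - 1), sample(1:2, 1), replace = TRUE)
      for (s in unique(src)) {
        g <- rdf_add(g, paste0("opredict:", ids[s]), "dul:precedes",
                     paste0("opredict:", ids[j]))
        edges <- rbind(edges, data.frame(from = s, to = j))
      }
    }
    ord <- repurpose:::local_name(step_order(g, "1.0"))
    pos <- match(ids, ord)
    # independent check: every edge goes forward in the returned order
    expect_true(all(pos[edges$from] < pos[edges$to]), label = paste("dag", k))
    expect_setequal(ord, ids)
  }
})

test_that("version diffs classify plans as removed, changed or added", {
  fx <- build_paper_fixture()
  d0 <- diff_versions(fx, "0.1", "0.1")
  expect_length(d0$removed, 0)
  expect_length(d0$changed, 0)
  expect_length(d0$added, 0)

  # constructed graph: 2 reused, 1 revised, 1 dropped, 1 new
  g <- rdf_graph()
  add_wf <- function(g, wf, ver, steps, plans) {
    g <- rdf_add(g, wf, "rdf:type", c("p-plan:Plan", "dul:Workflow"))
    g <- rdf_add(g, wf, "dc:hasVersion", ver, o_iri = FALSE)
    g <- rdf_add(g, wf, "pwo:hasFirstStep", steps[1])
    for (i in seq_along(steps)) {
      g <- rdf_add(g, steps[i], "rdf:type", "p-plan:Step")
      g <- rdf_add(g, steps[i], "p-plan:isStepOfPlan", wf)
      g <- rdf_add(g, steps[i], "dul:isDescribedBy", plans[i])
      g <- rdf_add(g, plans[i], "rdf:type", "p-plan:Plan")
    }
    g
  }
  g <- add_wf(g, "opredict:WF1", "1",
              paste0("opredict:S1_", 1:4),
              paste0("opredict:P_", c("keep1", "keep2", "old", "dropped")))
  g <- add_wf(g, "opredict:WF2", "2",
              paste0("opredict:S2_", 1:4),
              paste0("opredict:P_", c("keep1", "keep2", "newrev", "brandnew")))
  g <- rdf_add(g, "opredict:P_newrev", "prov:wasRevisionOf", "opredict:P_old")
  d <- diff_versions(g, "1", "2")
  expect_equal(repurpose:::local_name(d$removed), "P_dropped")
  expect_equal(repurpose:::local_name(d$changed), "P_newrev")
  expect_equal(repurpose:::local_name(d$added), "P_brandnew")
  # pairwise disjoint by definition
  expect_length(intersect(d$removed, d$changed), 0)
  expect_length(intersect(d$removed, d$added), 0)
  expect_length(intersect(d$changed, d$added), 0)
  expect_error(diff_versions(g, "1", "7"), "unknown workflow")

  # fixture: the automatized interactome download is the one changed plan
  r32 <- answer_cq(fx, "3.2", list(v_old = "0.1", v_new = "0.2"))
  changed <- r32$rows$plan[r32$rows$status == "changed"]
  expect_equal(repurpose:::local_name(changed), "Plan_Download_human_interactome_v02")
  r33 <- answer_cq(fx, "3.3", list(v_old = "0.1", v_new = "0.2"))
  expect_equal(repurpose:::local_name(r33$rows$old_step), "Step_Download_human_interactome")
})

test_that("emitted workflows are recovered exactly by CQ1.1 (emit-then-query)", {
  for (seed in c(71, 72, 73, 74, 75)) {
    spec <- random_workflow_spec(seed)
    g <- describe_workflow(spec)
    r <- answer_cq(g, "1.1", list(workflow = spec$version))
    expect_equal(nrow(r$rows), length(spec$steps))
    got <- r$rows$kind[order(repurpose:::local_name(r$rows$step))]
    want <- vapply(spec$steps, `[[`, "", "kind")
    want <- want[order(vapply(spec$steps, `[[`, "", "id"))]
    expect_identical(got, want, label = paste("spec seed", seed))
  }
})

test_that("CQ3.5 recovers exactly the metrics of a recorded execution", {
  spec <- random_workflow_spec(81, n_steps = 3)
  metrics <- c(Accuracy = 0.91, RocAuc = 0.88, F1 = 0.86)
  run <- run_record("424242",
                    activities = data.frame(
                      step_id = vapply(spec$steps, `[[`, "", "id"),
                      start = NA_character_, end = NA_character_,
                      stringsAsFactors = FALSE),
                    metrics = metrics,
                    generated_at = "2020-01-01T00:00:00.000")
  g <- repurpose:::rdf_merge(describe_workflow(spec), record_execution(spec, run))
  r <- answer_cq(g, "3.5")
  vals <- r$rows[!is.na(r$rows$artifact), ]
  expect_equal(nrow(vals), 3)
  got <- stats::setNames(as.numeric(vals$value),
                         sub("^EvaluationMeasure_", "",
                             repurpose:::local_name(vals$measure)))
  expect_equal(got[names(metrics)], metrics, tolerance = 1e-6)
  expect_true(all(vals$version == spec$version))
})
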