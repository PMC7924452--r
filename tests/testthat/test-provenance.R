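four_step_spec <- function() {
  workflow_spec(
    id = "Plan_Test_Protocol_v01", version = "0.1",
    label = "Test protocol", created = "2020-02-02",
    steps = list(
      step_spec("Step_A_download", "Download dataset", kind = "manual",
                operation = "edam:operation_2409",
                outputs = "Variable_raw",
                datasets = c(Variable_raw = "Distribution_raw")),
      step_spec("Step_B_features", "Feature generation", kind = "script",
                language = "Python 3.5",
                inputs = "Variable_raw", outputs = "Variable_features"),
      step_spec("Step_C_train", "Model training", kind = "script",
                language = "Python 3.5", inputs = "Variable_features",
                agents = c(Agent_dev = "Developer")),
      step_spec("Step_D_present", "Present results", kind = "manual")
    ),
    distributions = list(
      dataset_distribution("Distribution_raw", "raw table",
                           download_url = "http://example.org/raw.tsv",
                           media_type = "DataFormat_tsv"))
  )
}

test_that("prospective emission types steps and orders them as specified", {
  g <- describe_workflow(four_step_spec())
  ord <- step_order(g, "0.1")
  expect_length(ord, 4)
  expect_identical(repurpose:::local_name(ord),
                   c("Step_A_download", "Step_B_features",
                     "Step_C_train", "Step_D_present"))
  # the manual download step bears both the task class and the EDAM class
  ty <- rdf_match(g, s = "opredict:Step_A_download", p = "rdf:type")$o
  expect_true(expand_iri("bpmn:ManualTask", g$prefixes) %in% ty)
  expect_true(expand_iri("edam:operation_2409", g$prefixes) %in% ty)
  # every step has exactly one describing plan
  for (s in ord) {
    expect_equal(nrow(rdf_match(g, s = s, p = "dul:isDescribedBy")), 1)
  }
  # the first step has no predecessor
  expect_equal(nrow(rdf_match(g, p = "dul:precedes", o = ord[1])), 0)
  # dataset binding via qualified usage, with URL on the distribution
  expect_equal(nrow(rdf_match(g, p = "prov:qualifiedUsage")), 1)
  expect_equal(rdf_match(g, s = "opredict:Distribution_raw",
                         p = "dcat:downloadURL")$o, "http://example.org/raw.tsv")
  # agent role association
  assoc <- rdf_match(g, p = "rdf:type", o = "prov:Association")$s
  expect_length(assoc, 1)
  expect_equal(repurpose:::local_name(rdf_match(g, s = assoc, p = "prov:hadRole")$o),
               "Role_Developer")
})

test_that("a spec without datasets emits no distribution nodes", {
  spec <- workflow_spec(id = "Plan_NoData", version = "0.1",
                        steps = list(step_spec("Step_only", kind = "script")))
  g <- describe_workflow(spec)
  expect_equal(nrow(rdf_match(g, p = "rdf:type", o = "dcat:Distribution")), 0)
})

test_that("retrospective emission carries one artifact per metric, recoverable after round-trip", {
  spec <- four_step_spec()
  metrics <- c(Accuracy = 0.833336, AveragePrecision = 0.81, F1 = 0.79,
               Precision = 0.77, Recall = 0.82, RocAuc = 0.87)
  run <- run_record("1546302862",
                    activities = data.frame(
                      step_id = vapply(spec$steps, `[[`, "", "id"),
                      start = paste0("2019-01-01T00:00:0", 0:3, ".000"),
                      end = paste0("2019-01-01T00:00:0", 1:4, ".000"),
                      stringsAsFactors = FALSE),
                    metrics = metrics, generated_at = "2019-01-01T00:02:31.011")
  g <- record_execution(spec, run)
  acts <- rdf_match(g, p = "rdf:type", o = "p-plan:Activity")$s
  expect_length(acts, 4)
  # every activity corresponds to exactly one spec step
  for (a in acts) {
    expect_equal(nrow(rdf_match(g, s = a, p = "p-plan:correspondsToStep")), 1)
  }
  gen <- rdf_match(g, p = "prov:generated")
  expect_equal(nrow(gen), 6)  # the six standard measures
  # round-trip then re-read metric values through the graph
  g2 <- parse_turtle(serialize_turtle(g))
  expect_true(rdf_isomorphic(g, g2))
  for (m in names(metrics)) {
    art <- paste0("opredict:ModelEvaluation_", m, "_Execution_1546302862")
    val <- rdf_match(g2, s = art, p = "dc:description", o_iri = FALSE)$o
    expect_equal(as.numeric(val), unname(metrics[m]), tolerance = 1e-6)
  }
  expect_error(record_execution(spec, run_record("x", data.frame(step_id = "nope"))),
               "unknown step")
  # empty run: empty retrospective graph
  empty <- record_execution(spec, run_record("y", data.frame(step_id = character(0))))
  expect_equal(rdf_size(empty), 0)
})

test_that("revision links carry both version literals and reject self-revision", {
  v1 <- four_step_spec()
  v2 <- workflow_spec(
    id = "Plan_Test_Protocol_v02", version = "0.2", created = "2020-03-03",
    steps = list(
      step_spec("Step_A_download_v02", "Download dataset (scripted)",
                kind = "script", language = "Python 3.5",
                revises = "Step_A_download"),
      step_spec("Step_B_features", "Feature generation", kind = "script",
                language = "Python 3.5")
    ))
  g <- link_revision(v2, v1)
  expect_equal(nrow(rdf_match(g, s = "opredict:Plan_Test_Protocol_v02",
                              p = "prov:wasRevisionOf",
                              o = "opredict:Plan_Test_Protocol_v01")), 1)
  expect_setequal(rdf_match(g, p = "dc:hasVersion", o_iri = FALSE)$o, c("0.1", "0.2"))
  expect_equal(nrow(rdf_match(g, s = "opredict:Plan_Step_A_download_v02",
                              p = "prov:wasRevisionOf")), 1)
  expect_error(link_revision(v1, v1), "cannot revise itself")
})

test_that("Turtle serialization round-trips randomly generated graphs", {
  set.seed(53)
  preds <- c("rdf:type", "rdfs:label", "dc:description", "dul:precedes",
             "prov:generated", "dcat:downloadURL")
  for (k in 1:100) {
    g <- rdf_graph()
    n <- sample(1:12, 1)
    for (i in seq_len(n)) {
      s <- paste0("opredict:Node_", sample(8, 1))
      p <- sample(preds, 1)
      if (runif(1) < 0.5) {
        g <- rdf_add(g, s, p, paste0("opredict:Node_", sample(8, 1)))
      } else {
        o <- rawToChar(as.raw(sample(32:126, sample(1:12, 1), replace = TRUE)))
        dt <- if (runif(1) < 0.3) "xsd:string" else NA_character_
        g <- rdf_add(g, s, p, o, o_iri = FALSE, dt = dt)
      }
    }
    g2 <- parse_turtle(serialize_turtle(g))
    expect_true(rdf_isomorphic(g, g2), label = paste("random graph", k))
  }
})

test_that("literals with quotes, newlines and backslashes survive the round-trip", {
  g <- rdf_add(rdf_graph(), "opredict:N", "dc:description",
               "a \"quoted\" value with \\ and\nnewline\tand tab", o_iri = FALSE)
  g2 <- parse_turtle(serialize_turtle(g))
  expect_true(rdf_isomorphic(g, g2))
})

test_that("an empty graph serializes to a prefix block only", {
  txt <- serialize_turtle(rdf_graph())
  lines <- strsplit(txt, "\n")[[1]]
  expect_true(all(grepl("^@prefix ", lines[nzchar(lines)])))
  expect_equal(rdf_size(parse_turtle(txt)), 0)
})

test_that("malformed Turtle is rejected with the offending line", {
  expect_error(parse_turtle("opredict:A rdf:type"), "line 1")
  expect_error(parse_turtle("@prefix foo <http://x> ."), "line 1")
  expect_error(parse_turtle("<http://a> <http://b> \"unterminated"), "line 1")
  expect_error(parse_turtle("undeclared:A <http://b> <http://c> ."), "undeclared prefix")
})

test_that("the worked-example fixture reproduces the printed listings", {
  fx <- build_paper_fixture()
  # DrugBank distribution download URL literal
  url <- rdf_match(fx, s = "opredict:Distribution_release-4-drugbank-drugbank.nq.gz",
                   p = "dcat:downloadURL")$o
  expect_equal(url, "http://download.bio2rdf.org/files/release/4/drugbank/drugbank.nq.gz")
  # accuracy model-evaluation for execution 1546302862
  acc <- rdf_match(fx, s = "opredict:ModelEvaluation_Accuracy_Execution_1546302862",
                   p = "dc:description", o_iri = FALSE)$o
  expect_equal(acc, "0.833336")
  # precedence: download before save
  expect_equal(nrow(rdf_match(fx, s = "opredict:Step_Download_Drugbank_dataset",
                              p = "dul:precedes",
                              o = "opredict:Step_Save_Drugbank_dataset")), 1)
  # generation timestamp with millisecond precision and dateTime type
  t <- rdf_match(fx, s = "opredict:Generation_Execution_1546302862", p = "prov:atTime")
  expect_equal(t$o, "2019-01-01T00:02:31.011")
  expect_equal(t$dt, expand_iri("xsd:dateTime", fx$prefixes))
  # workflow-level revision triple and version literals
  expect_equal(nrow(rdf_match(fx, s = "opredict:Plan_Main_Protocol_v02",
                              p = "prov:wasRevisionOf",
                              o = "opredict:Plan_Main_Protocol_v01")), 1)
  expect_setequal(rdf_match(fx, p = "dc:hasVersion", o_iri = FALSE)$o, c("0.1", "0.2"))
  # fixture serialization re-parses identically
  expect_true(rdf_isomorphic(fx, parse_turtle(serialize_turtle(fx))))
})
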