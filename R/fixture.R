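#' Worked-example provenance graph
#'
#' Builds the fixture graph used throughout the documentation and the
#' competency-question tests: a two-version drug-repurposing workflow with
#' prospective provenance (a manual DrugBank-download step with its
#' instruction plan, qualified variable binding and dataset distribution),
#' retrospective provenance (a model-training execution generating the six
#' evaluation-measure artifacts, the accuracy one valued `0.833336`), and
#' version links between protocol v0.1 and v0.2. Beyond those worked
#' examples the graph carries the glue triples (step typings, plan links,
#' abstraction and association examples, a manual-to-script revision and a
#' v0.2-only dataset) that make every competency question answerable on it.
#'
#' @param base IRI base for minted namespaces.
#' @return an `rdf_graph`.
#' @export
build_paper_fixture <- function(base = "https://w3id.org/fair/plex") {
  g <- rdf_graph(default_prefixes(base))
  lit <- function(g, s, p, o) rdf_add(g, s, p, o, o_iri = FALSE)

  ## --- prospective worked example: the DrugBank download step ----------
  s_dl <- "opredict:Step_Download_Drugbank_dataset"
  g <- rdf_add(g, s_dl, "rdf:type",
               c("bpmn:ManualTask", "edam:operation_2409", "p-plan:Step"))
  g <- rdf_add(g, s_dl, "p-plan:hasOutputVar", "opredict:Variable_Drugbank_dataset_online")
  g <- rdf_add(g, s_dl, "p-plan:isStepOfPlan", "opredict:Plan_Main_Protocol_v01")
  g <- rdf_add(g, s_dl, "dul:isDescribedBy", "opredict:Plan_Download_Drugbank_dataset")
  g <- rdf_add(g, s_dl, "dul:precedes", "opredict:Step_Save_Drugbank_dataset")
  g <- lit(g, s_dl, "rdfs:label", "Download Drugbank dataset")

  p_dl <- "opredict:Plan_Download_Drugbank_dataset"
  g <- rdf_add(g, p_dl, "rdf:type", "p-plan:Plan")
  g <- lit(g, p_dl, "dc:description", "Download Drugbank dataset")
  g <- rdf_add(g, p_dl, "dc:language", "opredict:LinguisticSystem_xsd_language_English")
  g <- lit(g, p_dl, "rdfs:label", "Download Drugbank dataset")
  g <- rdf_add(g, p_dl, "prov:qualifiedUsage",
               "opredict:Usage_Fetch_download_Drugbank_dataset_to_variable")

  usage <- "opredict:Usage_Fetch_download_Drugbank_dataset_to_variable"
  g <- rdf_add(g, usage, "rdf:type", "prov:Usage")
  g <- lit(g, usage, "rdfs:label", "Link variable to download Drugbank dataset")
  g <- rdf_add(g, usage, "prov:entity",
               c("opredict:Distribution_release-4-drugbank-drugbank.nq.gz",
                 "opredict:Variable_Drugbank_dataset_online"))

  dist <- "opredict:Distribution_release-4-drugbank-drugbank.nq.gz"
  g <- rdf_add(g, dist, "rdf:type", "dcat:Distribution")
  g <- lit(g, dist, "rdfs:label", "release/4/drugbank/drugbank.nq.gz")
  g <- lit(g, dist, "dcat:downloadURL",
           "http://download.bio2rdf.org/files/release/4/drugbank/drugbank.nq.gz")
  g <- rdf_add(g, dist, "dcat:mediaType", "opredict:DataFormat_nq_compressed_gz")

  g <- rdf_add(g, "opredict:Variable_Drugbank_dataset_online", "rdf:type", "p-plan:Variable")
  g <- lit(g, "opredict:Variable_Drugbank_dataset_online", "rdfs:label",
           "Drugbank dataset online")

  g <- rdf_add(g, "opredict:LinguisticSystem_xsd_language_English",
               "rdf:type", "dc:LinguisticSystem")

  ## --- retrospective worked example: execution 1546302862 --------------
  act <- "opredict:Activity_Model_preparation_train_and_evaluation_Execution_1546302862"
  g <- rdf_add(g, act, "rdf:type", "p-plan:Activity")
  g <- rdf_add(g, act, "p-plan:correspondsToStep",
               "opredict:Step_Model_preparation_train_and_evaluation")
  evals <- c("opredict:ModelEvaluation_Accuracy_Execution_1546302862",
             "opredict:ModelEvaluation_AveragePrecision_Execution_1546302862",
             "opredict:ModelEvaluation_F1_Execution_1546302862",
             "opredict:ModelEvaluation_Precision_1546302862",
             "opredict:ModelEvaluation_Recall_Execution_1546302862",
             "opredict:ModelEvaluation_RocAuc_Execution_1546302862")
  g <- rdf_add(g, act, "prov:generated", evals)
  acc <- evals[1]
  g <- rdf_add(g, acc, "rdf:type", "mls:ModelEvaluation")
  g <- lit(g, acc, "dc:description", "0.833336")
  g <- rdf_add(g, acc, "mls:specifiedBy", "opredict:EvaluationMeasure_PredictiveAccuracy")
  g <- rdf_add(g, acc, "prov:qualifiedGeneration", "opredict:Generation_Execution_1546302862")
  # the remaining artifacts: typed, measured, but no printed value
  for (e in evals[-1]) {
    g <- rdf_add(g, e, "rdf:type", "mls:ModelEvaluation")
    g <- rdf_add(g, e, "prov:qualifiedGeneration", "opredict:Generation_Execution_1546302862")
  }
  g <- rdf_add(g, "opredict:EvaluationMeasure_PredictiveAccuracy",
               "rdf:type", "mls:EvaluationMeasure")
  gen <- "opredict:Generation_Execution_1546302862"
  g <- rdf_add(g, gen, "rdf:type", "prov:Generation")
  g <- rdf_add(g, gen, "prov:atTime", "2019-01-01T00:02:31.011",
               o_iri = FALSE, dt = "xsd:dateTime")

  ## --- versioning worked example: protocol v0.1 and v0.2 ---------------
  v02 <- "opredict:Plan_Main_Protocol_v02"
  g <- rdf_add(g, v02, "rdf:type", c("p-plan:Plan", "dul:Workflow"))
  g <- lit(g, v02, "dc:created", "2019-05-15")
  g <- rdf_add(g, v02, "dc:creator", "opredict:Agent_Remzi")
  g <- lit(g, v02, "dc:description", "OpenPREDICT Main Protocol v.0.2")
  g <- lit(g, v02, "dc:hasVersion", "0.2")
  g <- rdf_add(g, v02, "dc:language", "opredict:LinguisticSystem_xsd_language_English")
  g <- lit(g, v02, "dc:modified", "2019-07-03")
  g <- rdf_add(g, v02, "pwo:hasFirstStep", "opredict:Step_Prepare_Input_Data_Files_v02")
  g <- lit(g, v02, "rdfs:label", "Main Protocol v.0.2")
  g <- rdf_add(g, v02, "prov:wasAttributedTo", "opredict:Agent_Remzi")
  g <- rdf_add(g, v02, "prov:wasRevisionOf", "opredict:Plan_Main_Protocol_v01")

  v01 <- "opredict:Plan_Main_Protocol_v01"
  g <- rdf_add(g, v01, "rdf:type", c("p-plan:Plan", "dul:Workflow"))
  g <- lit(g, v01, "dc:created", "2018-11-27")
  g <- rdf_add(g, v01, "dc:creator", "opredict:Agent_Remzi")
  g <- lit(g, v01, "dc:description", "OpenPREDICT Main Protocol v.0.1")
  g <- lit(g, v01, "dc:hasVersion", "0.1")
  g <- rdf_add(g, v01, "dc:language", "opredict:LinguisticSystem_xsd_language_English")
  g <- lit(g, v01, "dc:modified", "2019-05-15")
  g <- rdf_add(g, v01, "pwo:hasFirstStep", "opredict:Step_Prepare_Input_Data_Files")
  g <- lit(g, v01, "rdfs:label", "Main Protocol v.0.1")
  g <- rdf_add(g, v01, "prov:wasAttributedTo", "opredict:Agent_Remzi")

  g <- rdf_add(g, "opredict:Agent_Remzi", "rdf:type", "prov:Agent")

  ## --- glue: step/plan scaffolding making every CQ answerable ----------
  add_step <- function(g, id, wf, kind, label, language = "English",
                       precedes = NULL, operation = NULL, described_by = NULL) {
    s <- paste0("opredict:Step_", id)
    plan <- paste0("opredict:Plan_", id)
    g <- rdf_add(g, s, "rdf:type", c("p-plan:Step", task_class(kind)))
    if (!is.null(operation)) g <- rdf_add(g, s, "rdf:type", operation)
    g <- rdf_add(g, s, "p-plan:isStepOfPlan", wf)
    g <- rdf_add(g, s, "dul:isDescribedBy", plan)
    g <- lit(g, s, "rdfs:label", label)
    if (!is.null(precedes)) {
      g <- rdf_add(g, s, "dul:precedes", paste0("opredict:Step_", precedes))
    }
    g <- rdf_add(g, plan, "rdf:type", "p-plan:Plan")
    g <- lit(g, plan, "dc:description", label)
    g <- rdf_add(g, plan, "dc:language",
                 paste0("opredict:LinguisticSystem_xsd_language_",
                        gsub("[^A-Za-z0-9]+", "_", language)))
    if (!is.null(described_by)) {
      g <- rdf_add(g, plan, "dul:isDescribedBy", paste0("opredict:Plan_", described_by))
    }
    g
  }

  # v0.1 main chain (the four top-level steps)
  g <- add_step(g, "Prepare_Input_Data_Files", v01, "manual",
                "Prepare input data files", operation = "edam:operation_2409",
                precedes = "Feature_generation_Pipeline_OpenPREDICT_ipynb")
  g <- add_step(g, "Feature_generation_Pipeline_OpenPREDICT_ipynb", v01, "script",
                "Feature generation", language = "Python 3.5",
                precedes = "Model_preparation_train_and_evaluation")
  g <- add_step(g, "Model_preparation_train_and_evaluation", v01, "script",
                "Model preparation, train and evaluation", language = "Python 3.5",
                precedes = "Format_results_for_presentation")
  g <- add_step(g, "Format_results_for_presentation", v01, "manual",
                "Format results for presentation")
  # v0.1 data-preparation sub-steps (download step already emitted above)
  g <- add_step(g, "Save_Drugbank_dataset", v01, "manual",
                "Save Drugbank dataset", operation = "edam:operation_2409")
  g <- add_step(g, "Download_human_interactome", v01, "manual",
                "Download human interactome", operation = "edam:operation_2409")

  # abstraction example: two notebook-cell plans instantiate one
  # specification plan, with the association who made the instantiation
  spec_plan <- "opredict:Plan_Load_features_specification"
  g <- rdf_add(g, spec_plan, "rdf:type", "p-plan:Plan")
  g <- lit(g, spec_plan, "dc:description", "Load all features and gold standard")
  g <- rdf_add(g, spec_plan, "dc:language",
               "opredict:LinguisticSystem_xsd_language_English")
  for (cell in c("Feature_generation_01_Pipeline_Source_Cell11",
                 "Feature_generation_01_Pipeline_Source_Cell12")) {
    g <- add_step(g, cell, v01, "script", gsub("_", " ", cell),
                  language = "Python 3.5")
    g <- rdf_add(g, paste0("opredict:Plan_", cell), "dul:isDescribedBy", spec_plan)
  }
  assoc <- "opredict:Association_Remzi_Developer"
  g <- rdf_add(g, assoc, "rdf:type", "prov:Association")
  g <- rdf_add(g, assoc, "prov:agent", "opredict:Agent_Remzi")
  g <- rdf_add(g, assoc, "prov:hadRole", "opredict:Role_Developer")
  g <- rdf_add(g, "opredict:Role_Developer", "rdf:type", "prov:Role")
  g <- rdf_add(g, assoc, "prov:hadPlan",
               c(p_dl, spec_plan,
                 "opredict:Plan_Feature_generation_01_Pipeline_Source_Cell11",
                 "opredict:Plan_Feature_generation_01_Pipeline_Source_Cell12"))
  # executor of the manual download/save steps
  assoc2 <- "opredict:Association_Joao_Executor"
  g <- rdf_add(g, assoc2, "rdf:type", "prov:Association")
  g <- rdf_add(g, assoc2, "prov:agent", "opredict:Agent_Joao")
  g <- rdf_add(g, "opredict:Agent_Joao", "rdf:type", "prov:Agent")
  g <- rdf_add(g, assoc2, "prov:hadRole", "opredict:Role_Executor")
  g <- rdf_add(g, "opredict:Role_Executor", "rdf:type", "prov:Role")
  g <- rdf_add(g, assoc2, "prov:hadPlan",
               c(p_dl, "opredict:Plan_Save_Drugbank_dataset",
                 "opredict:Plan_Download_human_interactome"))

  # v0.2: new preparation step (reuses feature-generation instruction) and
  # the automatized (manual -> script) interactome download
  g <- add_step(g, "Prepare_Input_Data_Files_v02", v02, "script",
                "Prepare input data files (scripted)", language = "Python 3.5",
                operation = "edam:operation_2409",
                precedes = "Feature_generation_v02")
  s_fg2 <- "opredict:Step_Feature_generation_v02"
  g <- rdf_add(g, s_fg2, "rdf:type", c("p-plan:Step", "bpmn:ScriptTask"))
  g <- rdf_add(g, s_fg2, "p-plan:isStepOfPlan", v02)
  g <- rdf_add(g, s_fg2, "dul:isDescribedBy",
               "opredict:Plan_Feature_generation_Pipeline_OpenPREDICT_ipynb")
  g <- lit(g, s_fg2, "rdfs:label", "Feature generation")
  g <- add_step(g, "Download_human_interactome_v02", v02, "script",
                "Download human interactome (scripted)", language = "Python 3.5",
                operation = "edam:operation_2409")
  g <- rdf_add(g, "opredict:Plan_Download_human_interactome_v02",
               "prov:wasRevisionOf", "opredict:Plan_Download_human_interactome")

  # v0.2-only dataset binding (the MeSH annotation table)
  p_hi2 <- "opredict:Plan_Download_human_interactome_v02"
  usage2 <- "opredict:Usage_Fetch_mim2mesh_to_variable"
  g <- rdf_add(g, p_hi2, "prov:qualifiedUsage", usage2)
  g <- rdf_add(g, usage2, "rdf:type", "prov:Usage")
  g <- rdf_add(g, usage2, "prov:entity",
               c("opredict:Distribution_mim2mesh.tsv",
                 "opredict:Variable_mim2mesh_online"))
  g <- rdf_add(g, "opredict:Variable_mim2mesh_online", "rdf:type", "p-plan:Variable")
  d2 <- "opredict:Distribution_mim2mesh.tsv"
  g <- rdf_add(g, d2, "rdf:type", "dcat:Distribution")
  g <- lit(g, d2, "rdfs:label", "mim2mesh.tsv")
  g <- lit(g, d2, "dcat:downloadURL",
           "http://www.paccanarolab.org/static_content/disease_similarity/mim2mesh.tsv")
  g <- rdf_add(g, d2, "dcat:mediaType", "opredict:DataFormat_tsv")

  # v0.1 usage of the DrugBank distribution reaches CQ1.3 through the
  # manual download plan (emitted above); variable binding of the save step
  g <- rdf_add(g, "opredict:Step_Save_Drugbank_dataset", "p-plan:hasInputVar",
               "opredict:Variable_Drugbank_dataset_online")
  g <- rdf_add(g, "opredict:Step_Download_human_interactome", "p-plan:hasOutputVar",
               "opredict:Variable_Human_interactome_online")
  g <- rdf_add(g, "opredict:Variable_Human_interactome_online",
               "rdf:type", "p-plan:Variable")
  g
}
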