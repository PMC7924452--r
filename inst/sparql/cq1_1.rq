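# CQ1.1 Which steps are meant to be executed manually and which computationally?
# Substitute ?workflow (the versioned workflow IRI) before execution.
SELECT ?step ?stepType ?plan WHERE {
  ?step p-plan:isStepOfPlan ?workflow ;
        rdf:type ?stepType ;
        dul:isDescribedBy ?plan .
  VALUES ?stepType { bpmn:ManualTask bpmn:ScriptTask }
} ORDER BY ?step
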