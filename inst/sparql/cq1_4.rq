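# CQ1.4 What are the types of manual steps, and their inputs and outputs?
SELECT ?step ?operation ?inVar ?outVar WHERE {
  ?step p-plan:isStepOfPlan ?workflow ;
        rdf:type bpmn:ManualTask .
  OPTIONAL { ?step rdf:type ?operation .
             FILTER STRSTARTS(STR(?operation), STR(edam:)) }
  OPTIONAL { ?step p-plan:hasInputVar ?inVar }
  OPTIONAL { ?step p-plan:hasOutputVar ?outVar }
} ORDER BY ?step
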