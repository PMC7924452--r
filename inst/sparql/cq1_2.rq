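# CQ1.2 For the manual steps, who are the agents responsible to execute them?
SELECT ?step ?agent ?role WHERE {
  ?step p-plan:isStepOfPlan ?workflow ;
        rdf:type ?stepType ;
        dul:isDescribedBy ?plan .
  VALUES ?stepType { bpmn:ManualTask }
  ?association a prov:Association ;
               prov:hadPlan ?plan ;
               prov:agent ?agent ;
               prov:hadRole ?role .
} ORDER BY ?step ?agent ?role
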