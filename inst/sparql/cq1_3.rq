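# CQ1.3 Which datasets were manually handled and what are their formats?
SELECT ?step ?distribution ?url ?mediaType WHERE {
  ?step p-plan:isStepOfPlan ?workflow ;
        rdf:type bpmn:ManualTask ;
        dul:isDescribedBy ?plan .
  ?plan prov:qualifiedUsage ?usage .
  ?usage prov:entity ?distribution .
  ?distribution a dcat:Distribution ;
                dcat:downloadURL ?url .
  OPTIONAL { ?distribution dcat:mediaType ?mediaType }
} ORDER BY ?step ?distribution
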