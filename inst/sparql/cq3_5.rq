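# CQ3.5 Which workflow version was used in each execution and what was generated?
SELECT ?activity ?version ?artifact ?measure ?value WHERE {
  ?activity a p-plan:Activity ;
            p-plan:correspondsToStep ?step .
  ?step p-plan:isStepOfPlan ?workflow .
  ?workflow dc:hasVersion ?version .
  OPTIONAL {
    ?activity prov:generated ?artifact .
    OPTIONAL { ?artifact mls:specifiedBy ?measure }
    OPTIONAL { ?artifact dc:description ?value }
  }
} ORDER BY ?activity ?artifact
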