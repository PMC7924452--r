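# CQ3.2 Which instructions were removed from ?oldWorkflow to ?newWorkflow?
SELECT DISTINCT ?plan WHERE {
  ?oldStep p-plan:isStepOfPlan ?oldWorkflow ; dul:isDescribedBy ?plan .
  FILTER NOT EXISTS { ?newStep p-plan:isStepOfPlan ?newWorkflow ;
                               dul:isDescribedBy ?plan . }
  FILTER NOT EXISTS { ?newStep2 p-plan:isStepOfPlan ?newWorkflow ;
                               dul:isDescribedBy ?newPlan .
                      ?newPlan prov:wasRevisionOf ?plan . }
} ORDER BY ?plan
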