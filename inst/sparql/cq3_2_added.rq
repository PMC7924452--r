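# CQ3.2 Which instructions were added from ?oldWorkflow to ?newWorkflow?
SELECT DISTINCT ?plan WHERE {
  ?newStep p-plan:isStepOfPlan ?newWorkflow ; dul:isDescribedBy ?plan .
  FILTER NOT EXISTS { ?oldStep p-plan:isStepOfPlan ?oldWorkflow ;
                               dul:isDescribedBy ?plan . }
  FILTER NOT EXISTS { ?plan prov:wasRevisionOf ?oldPlan .
                      ?oldStep2 p-plan:isStepOfPlan ?oldWorkflow ;
                                dul:isDescribedBy ?oldPlan . }
} ORDER BY ?plan
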