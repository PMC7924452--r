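# CQ3.2 Which instructions were changed from ?oldWorkflow to ?newWorkflow?
SELECT DISTINCT ?newPlan ?oldPlan WHERE {
  ?newStep p-plan:isStepOfPlan ?newWorkflow ; dul:isDescribedBy ?newPlan .
  ?oldStep p-plan:isStepOfPlan ?oldWorkflow ; dul:isDescribedBy ?oldPlan .
  ?newPlan prov:wasRevisionOf ?oldPlan .
} ORDER BY ?newPlan
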