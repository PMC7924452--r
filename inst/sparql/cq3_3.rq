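# CQ3.3 Which steps were automatized from ?oldWorkflow to ?newWorkflow?
SELECT ?newPlan ?oldPlan ?newStep ?oldStep WHERE {
  ?newStep p-plan:isStepOfPlan ?newWorkflow ;
           rdf:type bpmn:ScriptTask ;
           dul:isDescribedBy ?newPlan .
  ?oldStep p-plan:isStepOfPlan ?oldWorkflow ;
           rdf:type bpmn:ManualTask ;
           dul:isDescribedBy ?oldPlan .
  ?newPlan prov:wasRevisionOf ?oldPlan .
} ORDER BY ?newStep
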