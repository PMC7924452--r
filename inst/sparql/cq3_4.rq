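# CQ3.4 Which datasets were removed/added between ?oldWorkflow and ?newWorkflow?
# (run once per direction, swapping the workflow bindings for "removed")
SELECT DISTINCT ?distribution WHERE {
  ?newStep p-plan:isStepOfPlan ?newWorkflow ; dul:isDescribedBy ?newPlan .
  ?newPlan prov:qualifiedUsage ?usage .
  ?usage prov:entity ?distribution .
  ?distribution a dcat:Distribution .
  FILTER NOT EXISTS {
    ?oldStep p-plan:isStepOfPlan ?oldWorkflow ; dul:isDescribedBy ?oldPlan .
    ?oldPlan prov:qualifiedUsage ?oldUsage .
    ?oldUsage prov:entity ?distribution .
  }
} ORDER BY ?distribution
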