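# CQ2.3 What higher-level description does a workflow step instantiate?
SELECT ?plan ?specification WHERE {
  ?plan a p-plan:Plan ; dul:isDescribedBy ?specification .
  ?specification a p-plan:Plan .
} ORDER BY ?plan
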