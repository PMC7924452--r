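# CQ2.4 Who or what made the instantiation of a higher-level description
# into an executable workflow step?
SELECT ?plan ?agent ?role WHERE {
  { ?plan a p-plan:Plan ; dul:isDescribedBy ?x . ?x a p-plan:Plan . }
  UNION
  { ?x a p-plan:Plan ; dul:isDescribedBy ?plan . ?plan a p-plan:Plan . }
  ?association a prov:Association ;
               prov:hadPlan ?plan ;
               prov:agent ?agent ;
               prov:hadRole ?role .
} ORDER BY ?plan ?agent
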