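# CQ2.2 What are the steps of a specific workflow and how are they described?
SELECT ?step ?plan ?language WHERE {
  ?step p-plan:isStepOfPlan ?workflow ;
        dul:isDescribedBy ?plan .
  OPTIONAL { ?plan dc:language ?language }
} ORDER BY ?step
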