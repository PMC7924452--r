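# CQ3.1 What are the existing versions of a workflow and their provenance?
SELECT ?workflow ?version ?created ?modified ?creator ?attributedTo ?revisionOf WHERE {
  ?workflow a dul:Workflow .
  OPTIONAL { ?workflow dc:hasVersion ?version }
  OPTIONAL { ?workflow dc:created ?created }
  OPTIONAL { ?workflow dc:modified ?modified }
  OPTIONAL { ?workflow dc:creator ?creator }
  OPTIONAL { ?workflow prov:wasAttributedTo ?attributedTo }
  OPTIONAL { ?workflow prov:wasRevisionOf ?revisionOf }
} ORDER BY ?version
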