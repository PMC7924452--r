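# CQ2.1 What are the main steps of a general workflow?
# First step via pwo:hasFirstStep, then the transitive dul:precedes chain.
SELECT ?step WHERE {
  ?workflow pwo:hasFirstStep ?first .
  ?first dul:precedes* ?step .
}
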