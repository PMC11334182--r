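# Controlled vocabularies for BioRECIPE validation and conversion.
# Terms are matched case-insensitively and stored in lower case.
entity_types:
  - protein
  - gene
  - rna
  - chemical
  - protein family
  - complex
  - biological process
signs:
  - positive
  - negative
connection_types:
  - direct
  - indirect
spontaneous:
  - none
  - increase
  - decrease
booleans:
  true_values: ["true", "1", "yes"]
  false_values: ["false", "0", "no"]
sif_relations:
  positive: ["activates", "activate", "positive", "+"]
  negative: ["inhibits", "inhibit", "negative", "-"]
triplet_predicates:
  positive: increases
  negative: decreases
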