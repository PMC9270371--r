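# Example dialect for an engine exporting e-value-like scores
# (smaller = more confident) with 0-based peptide positions and its own
# column names; edit to match the actual export of your engine version.
engine_name: evalue_engine
column_map:
  sequence_a: PepSeq1
  sequence_b: PepSeq2
  protein_a: Protein1
  protein_b: Protein2
  position_a: PepPos1
  position_b: PepPos2
  score: EValue
  decoy: Decoy
  link_type: LinkType
  site_a: LinkPos1
  site_b: LinkPos2
score_direction: lower_better
decoy_values: ["true", "decoy", "D"]
link_type_vocabulary:
  crosslink: [cross-link, crosslink]
  deadend: [mono-link]
  looplink: [loop-link]
  linear: [linear]
position_base: 0
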