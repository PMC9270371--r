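# Canonical dialect: the package's own CSV schema.
engine_name: canonical
column_map:
  sequence_a: sequence_a
  sequence_b: sequence_b
  protein_a: protein_a
  protein_b: protein_b
  position_a: position_a
  position_b: position_b
  score: score
  decoy: decoy
  link_type: link_type
  site_a: site_a
  site_b: site_b
  replicate: replicate
  spectrum_ref: spectrum_ref
score_direction: higher_better
decoy_values: ["TRUE", "1", "decoy"]
link_type_vocabulary:
  crosslink: [crosslink, xl, intra, inter]
  deadend: [deadend, dead-end, monolink, mono-link]
  looplink: [looplink, loop-link, loop]
  linear: [linear, common, single]
position_base: 1
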