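# Wild-type Chlamydomonas reinhardtii isolated centrioles.
name: cr-wildtype
wall_radius_nm: 110
n_triplets: 9
tubulin_length_nm: {mean: 495, sd: 33}
position: center
channels:
  POC16: {offset_nm: 0, coverage_pct: {mean: 41, sd: 11}}
  POB15: {offset_nm: 12, coverage_pct: {mean: 40, sd: 6}}
phenotype:
  ellipse_ratio: [1.0, 1.0]
  break_arc_deg: 0
  break_prevalence: 0
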