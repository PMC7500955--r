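# Human U2OS centrioles, control siRNA condition. Channel offsets are the
# radial positions of the inner-scaffold proteins relative to the tubulin
# wall (positive = toward the lumen); coverage is the axial extent of the
# inner scaffold as a fraction of the tubulin length.
name: hs-control
wall_radius_nm: 110
n_triplets: 9
tubulin_length_nm: {mean: 434, sd: 58}
position: center
channels:
  WDR90:   {offset_nm: 2,  coverage_pct: {mean: 57, sd: 13}}
  POC1B:   {offset_nm: 15, coverage_pct: {mean: 57, sd: 13}}
  FAM161A: {offset_nm: 22, coverage_pct: {mean: 57, sd: 13}}
  POC5:    {offset_nm: 27, coverage_pct: {mean: 57, sd: 13}}
  Centrin: {offset_nm: 28, coverage_pct: {mean: 57, sd: 13}}
phenotype:
  ellipse_ratio: [1.0, 1.0]
  break_arc_deg: 0
  break_prevalence: 0
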