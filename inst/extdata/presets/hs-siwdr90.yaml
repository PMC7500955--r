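# Human U2OS centrioles depleted of WDR90: slightly elongated barrels, a
# reduced inner-scaffold belt at the proximal end of the core region, a
# fraction of centrioles with a fractured microtubule wall, and loss of
# roundness in top views.
name: hs-siwdr90
wall_radius_nm: 110
n_triplets: 9
tubulin_length_nm: {mean: 500, sd: 65}
position: proximal
position_frac: 0.15
channels:
  POC1B: {offset_nm: 15, coverage_pct: {mean: 24, sd: 14}}
  POC5:  {offset_nm: 27, coverage_pct: {mean: 24, sd: 14}}
phenotype:
  ellipse_ratio: [0.70, 0.95]
  break_arc_deg: 60
  break_prevalence: 0.10
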