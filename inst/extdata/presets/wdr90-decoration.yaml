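# Microtubule decorated with WDR90 N-terminal domain / tubulin oligomers:
# periodic bumps along the lattice.
name: wdr90-decoration
period_nm: 8.5
n_repeats: 20
bump_fwhm_nm: 4
noise_sd: 0.1
sample_step_nm: 0.5
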