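# Minimal pipeline configuration: two conditions in fast aggregated mode.
mode: aggregated
conditions: [depression, diabetic_emergency]
seed: 1
n_weeks_pre: 166
n_weeks_post: 16
denominator: 1.0e6
ar_rho: 0.3
ar_sigma: 0.05
season_amplitude: 0.1
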