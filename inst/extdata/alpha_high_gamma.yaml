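# Alpha-high gamma coupling preset: 8-10 Hz phase band, 50-70 Hz amplitude
# band (60 Hz center +/- 10 Hz upper phase edge).
phase_band: [8, 10]
amp_band: [50, 70]
intensity: 1.0
width_fraction: 0.25
multimodality: monophasic
fs: 1000
n_trials: 30
trial_length_ms: 2500
noise_scale: 1.0
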