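# Theta-low gamma coupling preset: 5-7 Hz phase band, 33-47 Hz amplitude
# band (40 Hz center +/- 7 Hz upper phase edge).
phase_band: [5, 7]
amp_band: [33, 47]
intensity: 1.0
width_fraction: 0.25
multimodality: monophasic
fs: 1000
n_trials: 30
trial_length_ms: 2500
noise_scale: 1.0
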