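# Example scenario grid: list-valued keys are fully crossed.
n_sample: [250, 1000]
target_prevalence: [0.1, 0.5, 0.9]
sigma_scale: 1
trim_method: none
trim_delta: 0
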