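d_a: 0.143
gamma: 0.598
na: 2.99
qa: 0.612
VT: 0.383
noise_sd: 0.0005
noise_mean: 0.0
ext_input: 0.35
response_threshold: 0.76
resting_level: 0.0
max_cycles: 250
na_inh: 8.0
qa_inh: 0.49
d_w: 0.02
LT: 0.312
n_learning_trials: 20
effect_cycles: 50
clamp_motor: yes
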