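name: stroop
layers:
- name: ink_color
  level: sensory
  codes:
  - Ink red
  - Ink green
- name: visual_word
  level: sensory
  codes:
  - Word RED
  - Word GREEN
- name: auditory_word
  level: sensory
  codes:
  - Heard red
  - Heard green
- name: color
  level: feature
  codes:
  - RedColor
  - GreenColor
- name: word
  level: feature
  codes:
  - RedWord
  - GreenWord
- name: modality
  level: feature
  codes: Verbal
- name: task
  level: task
  codes:
  - T1
  - T2
- name: motor
  level: motor
  codes:
  - M1
  - M2
sensory_feature_map:
  RedColor: Ink red
  GreenColor: Ink green
  RedWord:
  - Word RED
  - Heard red
  GreenWord:
  - Word GREEN
  - Heard green
  Verbal:
  - Heard red
  - Heard green
effects:
  M1: Heard red
  M2: Heard green
task:
  rules:
  - stimulus: RedColor
    task: T1
    response:
    - RedWord
    - Verbal
  - stimulus: GreenColor
    task: T2
    response:
    - GreenWord
    - Verbal
weights:
  sensory_feature: 0.295
  feature_sensory: 0.914
  feature_task: 0.95
  task_feature: 0.975
  response_task: 0.466
  task_stimulus: 0.576
  pair: 0.6
  lateral: -1.93
params:
  d_a: 0.143
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
learning:
  d_w: 0.02
  LT: 0.312
  n_learning_trials: 20
  effect_cycles: 50
  clamp_motor: yes
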