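name: inverted_simon
layers:
- name: auditory_pitch
  level: sensory
  codes:
  - Auditory high
  - Auditory low
- name: auditory_location
  level: sensory
  codes:
  - Auditory left
  - Auditory right
- name: haptic_location
  level: sensory
  codes:
  - Haptic left
  - Haptic right
- name: visual_location
  level: sensory
  codes:
  - Light left
  - Light right
- name: pitch
  level: feature
  codes:
  - High
  - Low
- name: location
  level: feature
  codes:
  - Left
  - Right
- name: object
  level: feature
  codes:
  - Key
  - Light
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
  High: Auditory high
  Low: Auditory low
  Left:
  - Auditory left
  - Haptic left
  - Light left
  Right:
  - Auditory right
  - Haptic right
  - Light right
  Key:
  - Haptic left
  - Haptic right
  Light:
  - Light left
  - Light right
effects:
  M1:
  - Haptic left
  - Light right
  M2:
  - Haptic right
  - Light left
task:
  rules:
  - stimulus: High
    task: T1
    response:
    - Left
    - Key
  - stimulus: Low
    task: T2
    response:
    - Right
    - Key
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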