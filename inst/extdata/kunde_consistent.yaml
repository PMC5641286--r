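name: response_effect_compatibility
layers:
- name: visual_color
  level: sensory
  codes:
  - Visual red
  - Visual green
- name: auditory_intensity
  level: sensory
  codes:
  - Auditory loud
  - Auditory soft
- name: haptic_intensity
  level: sensory
  codes:
  - Haptic forceful
  - Haptic gentle
- name: color
  level: feature
  codes:
  - Red
  - Green
- name: intensity
  level: feature
  codes:
  - Forceful
  - Gentle
- name: object
  level: feature
  codes:
  - Sound
  - Key
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
  Red: Visual red
  Green: Visual green
  Forceful:
  - Auditory loud
  - Haptic forceful
  Gentle:
  - Auditory soft
  - Haptic gentle
  Sound:
  - Auditory loud
  - Auditory soft
  Key:
  - Haptic forceful
  - Haptic gentle
effects:
  M1:
  - Haptic forceful
  - Auditory loud
  M2:
  - Haptic gentle
  - Auditory soft
task:
  rules:
  - stimulus: Red
    task: T1
    response:
    - Forceful
    - Key
  - stimulus: Green
    task: T2
    response:
    - Gentle
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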