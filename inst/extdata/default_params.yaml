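# committed default / calibrated parameters of the two models
ibl:
  d: 0.5               # base-level decay rate (architecture default)
  s_act: 0.23          # instantaneous activation-noise scale (calibrated)
  tau: -5.0            # retrieval threshold: story facts always retrievable
  trial_interval: 0.002  # simulated seconds between repetitions (calibrated)
  init_activation: 6.0 # zero-order strategy chunk activation at repetition 1
rl:
  alpha: 0.2           # utility learning rate (architecture default)
  s_util: 3.0          # utility noise scale
  reward_correct: 20.0
  reward_wrong: 0.0
  initial_utilities: [100.0, 25.0, 5.0]  # zero-, first-, second-order entries
  chain_lengths: [1, 2, 3]  # productions per strategy beyond shared steps
  step_time: 5.5       # simulated seconds per production firing (calibrated)
cohort:
  n_children: 100
  n_reps: 100
  base_seed: 42
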