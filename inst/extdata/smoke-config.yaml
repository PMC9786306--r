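# Minimal smoke-test configuration for the fatigue-monitoring pipeline:
# three workers, two-minute activity bouts, a short four-bout unseen
# session, and a tiny sequence model. Entries override
# aftmon::pipeline_config() defaults.
simulation:
  n_subjects: 3
  duration_s: 120
  rof_interval_s: 120
  unseen_schedule:
    activity_id: [HAM, WALK, CDB, GUDVL]
    duration_s: [120, 120, 120, 120]
  unseen_rof_interval_s: 60
features:
  k: 15
model:
  L: 10
  stride: 5
  eval_stride: 5
  hidden: [8, 4]
  dense: 8
  dropout: 0.2
  epochs: 2
  batch_size: 64
  learning_rate: 0.003
  validation_split: 0
classify:
  model: DT
  subset: AFT
  folds: 5
  compare_subsets: no
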