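windows:
- [-1.0, 0.0]
subwindow_len_s: 0.5
subwindow_step_s: 0.05
bands:
  beta: 3
  alpha: 4
n_selected: 20
beta_penalty: 1
svm:
  gamma: ~
  cost_pos: 2
  cost_neg: 1
cv_folds: 3
selection_scope: per_fold
complexity: standard
target_fs: 250
synth:
  n_subjects: 1
  n_sessions: 2
  n_cycles: 3
seed: 5
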