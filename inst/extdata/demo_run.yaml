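# Demonstration pipeline configuration: reduced-geometry session (same
# 5 x 5 mm field, coarser sampling) plus the model sweep and radial
# statistics.
seed: 1
stages: [simulate, preprocess, measure, fit, model, radial, report]
acquisition:
  frame_rate: 10
  trial_duration: 4
  stim_onset: 0.5
  image_rows: 40
  image_cols: 40
  pixel_pitch: 0.125
  n_trials: 8
magnification: 0.022
model_S: [3, 5, 7, 10, 20, 30]
model_alpha: 1
radial_n_sites: 20
radial_jitter_sd: 10
radial_n_iter: 200
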