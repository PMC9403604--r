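# recursion-weight sweep over the canonical 7-value grid, desk scale
n_videos: 40
class_ratio: 0.5
rate: 60
resolution: [60, 80]
duration: 10
eccentric_fraction: 0.25
patients: 8
betas: [0.001, 0.005, 0.01, 0.05, 0.1, 0.25, 0.5]
backbone:
  name: tiny_mlp
  input_size: [15, 20]
  hidden: 32
  epochs: 40
  batch_size: 256
  learning_rate: 0.05
  momentum: 0.9
  seed: 1
voting:
  method: soft
  prob_threshold: 0.5
  video_threshold: 0.5
train_fraction: 0.75
seed: 7
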