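# minutes-scale end-to-end check: simulate -> filter -> train -> vote -> eval
n_videos: 40
class_ratio: 0.5
rate: 60
resolution: [60, 80]
duration: 10
eccentric_fraction: 0.25
patients: 8
betas: 0.25
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
  method: temporal
  run_length: 50
  prob_threshold: 0.5
  video_threshold: 0.5
train_fraction: 0.75
seed: 7
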