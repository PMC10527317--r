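seed: 1
output_dir: copdfuse_run
synthetic_data:
  n_samples: 300
  n_features: 24
  modality_signal: complementary
  outlier_fraction: 0.0167
  repeated_meas_rate: 0.05
  volume_shape:
  - 16
  - 32
  - 32
  label_balance: 0.5
pb_preprocess:
  k: 10
  n_sigma: 3.0
  target_time: 4.0
gnn:
  n_layers: 4
  hidden_dim: 16
  dropout: 0.1
  pooling_ratio: 0.5
  out_dim: 64
  lr: 0.003
  epochs: 200
  batch_size: 48
cnn:
  backbone: resnet_lite_3d
  out_dim: 64
  epochs: 15
  batch_size: 10
  augment: yes
fusion:
  rank: 4
  tokens: 8
  d_model: 32
  heads: 4
  lr: 0.001
  epochs: 10
  batch_size: 10
train_eval:
  mode: ratio_3_1_1
  folds: 5
  pretrain_ct: yes
  shortlist: 4
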