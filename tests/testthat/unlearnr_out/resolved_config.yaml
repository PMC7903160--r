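n_sites: 3.0
per_site_n: 100.0
size: 32.0
overlap_years: ~
confound_correlate: none
confound_fraction: 0.5
label_availability: 1.0
task: regression
mode: unlearn
alpha: 1.0
beta: 10.0
lr: 0.001
batch_size: 32.0
pretrain_epochs: 20.0
patience: 10.0
unlearn_epochs: 15.0
feature_dim: 32.0
width_scale: 0.5
hidden: 16.0
attach: A
n_classes: 4.0
seed: 1.0
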