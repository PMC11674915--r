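input_shape:
  height: 224
  width: 224
  channels: 3
stem_filters: 32
mim_branch_filters: 64
mim_repeats: 1
post_mim_filters: 128
post_mim_kernel: 3
dseb_filters: 64
se_ratio: 16
cm_h: 256
cm_d: 16
cm_k: 5
cm_p: 2
head_hidden_units:
- 256
n_classes: 3
bias: yes
bn_variant: stem_only
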