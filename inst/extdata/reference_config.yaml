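num_classes: 3
input_size:
- 3
- 224
- 224
widths:
- 32
- 64
- 128
- 256
blocks:
- 2
- 1
- 3
- 3
odconv:
  'n': 1
  gamma: 0.125
  kernel_attention: sigmoid
ca:
  r: 8
  bn_after_reduce: yes
fca:
  fusion: sum
  proj_width: 256
final_pool: avg
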