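# Canonical recording CSV: header `t,ax,ay,az`, seconds and g.
header: true
sep: ","
columns:
  t: 1
  ax: 2
  ay: 3
  az: 4
scale_to_g: 1
sampling_rate: null
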