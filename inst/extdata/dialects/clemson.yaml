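# Wrist recordings of the public pedometer dataset: 15 Hz, ±2 g, values in g.
# Layout: time (s), then the three acceleration axes.
header: false
sep: ","
columns:
  t: 1
  ax: 2
  ay: 3
  az: 4
scale_to_g: 1
sampling_rate: 15
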