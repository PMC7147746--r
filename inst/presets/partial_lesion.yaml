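# Synaptic model with a partial straight lesion (phi = 0 on a segment)
# beside the excitation disk: activity passes around the cut.
model: 2
total_time: 300
lesion:
  kind: partial_segment
  x0: 4.0
  y0: 1.5
  x1: 4.0
  y1: 4.5
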