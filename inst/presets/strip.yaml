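# Narrow strip for wavefront-speed parameter sweeps: 6 x 0.6 mm, excitation
# disk at one end, speed measured along the long axis.
model: 2
total_time: 160
domain:
  width: 6
  height: 0.6
  nx: 80
  center: [0.3, 0.3]
  radius: 0.3
probes:
  - {label: S1, x: 0.3, "y": 0.3}
  - {label: S2, x: 2.3, "y": 0.3}
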