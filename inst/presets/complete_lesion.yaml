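# Combined model with a complete full-height synaptic cut and modified
# potassium-sensitivity parameters: the elevated bath and leak make
# discharges weak and frequent, and potassium diffusing through the cut
# can recruit the far territory (silent when diffusion is blocked).
model: 3
total_time: 120
parameters:
  tau_K: 10
  gK_leak_over_gL: 3
  K_bath: 4
  K_o0: 4
  D_K: 2.0e-5
domain:
  Kbath_center: 7
  Kbath_periphery: 4
noise:
  mode: inhomogeneous
lesion:
  kind: complete_line
  x: 4.5
  style: edges
probes:
  - {label: S1, x: 3.0, "y": 3.0}
  - {label: S2, x: 4.1, "y": 3.0}
  - {label: S3, x: 5.3, "y": 3.0}
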