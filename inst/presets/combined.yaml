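# Both propagation mechanisms active (diffusion + synaptic spread).
model: 3
total_time: 550
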