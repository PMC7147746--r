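# Potassium-diffusion model on the standard 6 x 6 mm domain, reference parameters.
model: 1
total_time: 300
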