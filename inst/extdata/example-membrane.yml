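tier: membrane
alpha: 3
r_n: 0.95
F: 0.05
i: 1000
t_end: 150
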