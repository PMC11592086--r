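# Contraction envelope: ramp to 10% of MVC over 0.35 s, then hold.
times: [0, 0.05, 0.4, 2.0]
levels: [0, 0, 0.1, 0.1]
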