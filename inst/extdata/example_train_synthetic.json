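{"duration_ms":200,"times_ms":[14.25,37.8,61.02,88.4,120.55,143.1,170.9,191.33]}
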