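mz	intensity
81.0676	327.272
145.1012	182.374
244.1676	192.623
256.2596	461.112
368.4196	164.718
551.5019	102.556
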