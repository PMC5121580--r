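mz	intensity
81.0672	370.341
145.0994	199.387
244.1607	183.888
256.2597	535.106
368.4213	165.001
551.4994	100.383
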