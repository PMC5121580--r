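mz	intensity
81.0707	303.2068
145.1021	230.5115
244.1658	191.8844
256.2618	556.0886
368.4214	156.3552
551.4979	39.9287
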