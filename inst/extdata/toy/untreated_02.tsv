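mz	intensity
81.0709	188.5432
145.1014	266.2327
244.1626	212.0909
256.2621	474.6971
368.4188	101.9591
551.5010	88.6296
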