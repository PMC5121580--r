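mz	intensity
81.0717	308.0886
145.0997	209.6281
256.2571	546.5117
299.2590	219.6172
368.4213	186.8880
551.5010	68.8818
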