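mz	intensity
81.070	280.0122
145.098	255.4273
256.259	465.0221
299.257	162.4815
368.423	138.7830
551.500	99.7463
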