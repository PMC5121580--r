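mz	intensity
81.0691	264.6205
145.1013	187.1872
244.1673	174.2227
256.2606	302.7585
368.4184	152.1654
551.5032	90.8618
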