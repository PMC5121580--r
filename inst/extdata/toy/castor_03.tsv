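mz	intensity
81.0691	270.544
145.0999	150.480
256.2598	406.340
299.2589	187.832
368.4182	151.017
551.4991	98.730
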