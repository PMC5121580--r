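mz	intensity
81.068	363.4264
145.104	198.4801
256.259	552.2678
299.259	175.5889
368.420	185.3463
551.499	75.8303
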