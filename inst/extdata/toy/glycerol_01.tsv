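mz	intensity
81.0681	305.2975
93.0493	552.6533
145.1022	206.9771
185.0590	415.7390
256.2608	509.9685
368.4212	154.1507
551.5036	86.7307
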