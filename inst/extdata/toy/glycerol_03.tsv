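mz	intensity
81.0727	291.228
93.0510	590.755
145.1000	199.958
185.0655	380.389
256.2605	519.978
368.4181	144.307
551.4985	92.727
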