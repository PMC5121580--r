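mz	intensity
81.0701	326.6843
93.0498	622.2283
145.0980	195.2957
185.0593	370.5859
256.2592	578.4029
368.4217	162.7725
551.5019	93.6794
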