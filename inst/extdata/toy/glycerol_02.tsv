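mz	intensity
81.0701	306.0734
93.0498	574.3381
145.0997	240.5277
185.0623	371.9733
256.2630	578.7779
368.4196	139.5886
551.4974	81.1165
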