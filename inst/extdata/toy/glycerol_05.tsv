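mz	intensity
81.0728	298.8415
93.0503	603.6060
145.1024	239.6382
185.0631	412.3370
256.2616	533.8225
368.4167	146.5206
551.4989	72.3305
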