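mz	intensity
81.067	304.0500
145.097	223.1428
256.260	496.4546
299.258	184.2768
368.418	160.6994
551.500	78.1467
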