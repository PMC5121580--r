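Synthetic toy fixture: 15 tiny centroided peak lists (3 classes x 5
samples) generated by dartchemo's own simulator (seed 42) for smoke-testing
the file-mode pipeline. Not instrument data.
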