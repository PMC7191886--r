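2abfc33ad2ab115e99488086ec5c6294
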