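0.278 0.312 0.212 0.198
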