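>synthetic_carrier constructed context around the K-site reporter 13-mer (not a natural sequence)
MAGTSEYDSVTRQKEPRAPWGSHTELRAGDKPLVSAWNDF
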