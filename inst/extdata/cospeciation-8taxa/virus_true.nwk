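((((((virus06:0.02063894034,virus08:0.02063894034):0.09293711892,virus04:0.1135760593):0.08959192089,(virus05:0.06967694314,virus07:0.06967694314):0.133491037):0.03980132178,virus02:0.2429693019):0.0004225448834,virus03:0.2433918468):0.04290184049,virus01:0.2862936873);
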