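3
Properties=species:S:1:pos:R:3
O     0.0000000000    0.0000000000    0.0000000000
H     0.7569000000    0.0000000000    0.5868000000
H    -0.7569000000    0.0000000000    0.5868000000
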