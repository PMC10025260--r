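[C:1]([C:2]([H:5])([H:4])[H:3])([H:8])([H:7])[H:6]>>[C:1](=[C:2]([H:4])[H:3])([H:7])[H:6].[H:8][H:5]
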