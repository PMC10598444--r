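# synthetic fixture: two coupled 2-node feedback modules
x1, x2
x2, x1
y1, x1 | (x2 & y2)
y2, !x2 & y1
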