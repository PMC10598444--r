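# synthetic fixture: a 3-node cascade; the self-loop on a keeps its SCC trivial
a, a
b, a
c, b
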