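# synthetic fixture: q lists a non-essential regulator (r & !r contributes nothing)
p, q
q, p | (r & !r)
r, q
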