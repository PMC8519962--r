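Intermediate-grade
Intermediate grade
High-grade
High grade
Low-grade
Low grade
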