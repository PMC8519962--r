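Well-differentiated	Well differentiated
Poorly-differentiated	Poorly differentiated
Moderately-differentiated	Moderately differentiated
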