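Malignant transformation
Well-differentiated
Well differentiated
Poorly-differentiated
Poorly differentiated
Moderately-differentiated
Moderately differentiated
Undifferentiated
Malignant
Benign
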