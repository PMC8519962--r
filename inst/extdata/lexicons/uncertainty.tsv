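Highly likely
Highly suggestive
Consistent with
Compatible with
Keeping with
Indicative of
Suggestive of
Favoured
Inconclusive
Probable
Possible
Likely
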