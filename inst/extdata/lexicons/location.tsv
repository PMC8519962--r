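Mammary gland
Oral cavity
Anal sac
Anal region
Perianal
Forelimb
Hindlimb
Testicle
Axilla
Abdomen
Thorax
Spleen
Liver
Neck
Chest
Brain
Bladder
Skin
cutaneous	maps_to=Skin
Head
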