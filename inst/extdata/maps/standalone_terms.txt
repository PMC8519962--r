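Lipoma
Mast cell tumour
Lymphoma
Histiocytoma
Squamous cell carcinoma
Basal cell tumour
Melanoma
Melanocytic tumour
Osteosarcoma
Fibrosarcoma
Haemangiosarcoma
Soft tissue sarcoma
Seminoma
Mixed tumour
Simple tubulo-papillary carcinoma
Adenoma of the hepatoid glands
Hepatoid carcinoma
Anal sac carcinoma
Plasma cell tumour
Thyroid carcinoma
Meibomian adenoma
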