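Mesenchymal neoplasia	Soft tissue sarcoma
Mesenchymal neoplasia	Fibrosarcoma
Mesenchymal neoplasia	Haemangiosarcoma
Mesenchymal neoplasia	Osteosarcoma
Sarcoma	Soft tissue sarcoma
Sarcoma	Fibrosarcoma
Thyroid epithelial neoplasia	Thyroid carcinoma
Thyroid neoplasia	Thyroid carcinoma
Epithelial tumour	Thyroid carcinoma
Epithelial tumour	Squamous cell carcinoma
Carcinoma	Squamous cell carcinoma
Carcinoma	Thyroid carcinoma
Neoplasia	Lymphoma
Tumour	Mast cell tumour
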