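Simple intratubular tubulopapillary carcinoma
Adenocarcinoma of the mammary gland, tubulopapillary
Adenocarcinoma arising in mixed gland mammary
Adenocarcinoma arising in mixed mammary
Mixed mammary gland tumour
(hepatoid gland) adenocarcinoma
(hepatoid gland) adenoma
(hepatoid gland) carcinoma
(hepatoid, circumanal) gland adenocarcinoma
(hepatoid, circumanal) gland adenoma
(hepatoid, circumanal) gland carcinoma
Perianal (hepatoid) adenoma
Hepatoid gland adenoma
Hepatoid adenoma
Adenoma of the hepatoid glands
Hepatoid (perianal) carcinoma
Hepatoid carcinoma
adenocarcinoma of the anal sac apocrine glands
Anal sac carcinoma
adenocarcinoma of the apocrine glands
Apocrine ductal carcinoma
adenocarcinoma of the Parathyroid gland
Squamous cell carcinoma
Basal cell tumour
Mast cell tumour
MCT
Soft tissue sarcoma
Osteosarcoma
Fibrosarcoma
Haemangiosarcoma
Histiocytoma
Lipoma
Seminoma
Lymphoma
Meibomian adenoma
Islet cell carcinoma
Thyroid carcinoma
Thyroid epithelial neoplasia
Thyroid neoplasia
Melanocytic tumour
Melanoma
Plasmacytoma
Multiple myeloma
Epithelial neoplasia
Epithelial tumour
Mesenchymal neoplasia
hamartoma	excluded
tumour-like	excluded
epidermal cyst	excluded
follicular cyst	excluded
cyst	excluded
adenocarcinoma (anaplastic)
Adenocarcinoma
Carcinoma
Adenoma
Epithelioma
Sarcoma
Neoplasia
Neoplasm
Tumour
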