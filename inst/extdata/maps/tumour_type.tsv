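(hepatoid gland) adenoma	Adenoma of the hepatoid glands
(hepatoid, circumanal) gland adenoma	Adenoma of the hepatoid glands
Perianal (hepatoid) adenoma	Adenoma of the hepatoid glands
Hepatoid adenoma	Adenoma of the hepatoid glands
Hepatoid gland adenoma	Adenoma of the hepatoid glands
Adenoma of the hepatoid glands	Adenoma of the hepatoid glands
(hepatoid gland) carcinoma	Hepatoid carcinoma
(hepatoid gland) adenocarcinoma	Hepatoid carcinoma
(hepatoid, circumanal) gland carcinoma	Hepatoid carcinoma
(hepatoid, circumanal) gland adenocarcinoma	Hepatoid carcinoma
Hepatoid (perianal) carcinoma	Hepatoid carcinoma
adenocarcinoma of the anal sac apocrine glands	Anal sac carcinoma
adenocarcinoma of the apocrine glands	Anal sac carcinoma
MCT	Mast cell tumour
Mixed mammary gland tumour	Mixed tumour
Simple intratubular tubulopapillary carcinoma	Simple tubulo-papillary carcinoma
Adenocarcinoma of the mammary gland, tubulopapillary	Simple tubulo-papillary carcinoma
Epithelial neoplasia	Epithelial tumour
Neoplasm	Neoplasia
adenocarcinoma (anaplastic)	Adenocarcinoma
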