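# Per-laboratory dialect configuration: section keyword synonyms per assay
# type, and the assay-code -> assay-type map. Keyword matching is
# case-insensitive; phrases are stored uppercase by the loader.
lab_a:
  assay_codes:
    histology: ["HISTO", "HIST", "BIOPSY"]
    cytology: ["CYT", "FNA"]
  keywords:
    histology:
      diagnosis_start: ["DIAGNOSIS"]
      prognosis: ["PROGNOSIS"]
      clinical_history: ["CLINICAL HISTORY", "CLINICAL DIAGNOSIS"]
      histology: ["HISTOLOGY"]
      comments: ["COMMENTS", "COMMENT"]
    cytology:
      diagnosis_start: ["CYTOLOGICAL INTERPRETATION"]
      prognosis: ["PROGNOSIS"]
      clinical_history: ["CLINICAL HISTORY", "CLINICAL DIAGNOSIS"]
      histology: ["CYTOLOGICAL DESCRIPTION"]
      comments: ["COMMENTS", "COMMENT"]
lab_b:
  assay_codes:
    histology: ["HISTO", "HP-"]
    cytology: ["CYT", "FNA"]
  keywords:
    histology:
      diagnosis_start: ["DIAGNOSIS"]
      prognosis: ["PROGNOSIS"]
      clinical_history: ["CLINICAL HISTORY", "CLINICAL DIAGNOSIS"]
      histology: ["HISTOLOGY", "MICROSCOPIC DESCRIPTION"]
      comments: ["COMMENTS", "COMMENT"]
    cytology:
      diagnosis_start: ["CYTOLOGICAL INTERPRETATION"]
      prognosis: ["PROGNOSIS"]
      clinical_history: ["CLINICAL HISTORY", "CLINICAL DIAGNOSIS"]
      histology: ["CYTOLOGICAL DESCRIPTION", "MICROSCOPIC DESCRIPTION"]
      comments: ["COMMENTS", "COMMENT"]
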