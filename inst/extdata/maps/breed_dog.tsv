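Retriever, Labrador	Labrador Retriever
Labrador retriever	Labrador Retriever
Labrador	Labrador Retriever
Staffordshire bull terrier	Staffordshire Bull Terrier
Staffie	Staffordshire Bull Terrier
Cocker spaniel	Cocker Spaniel
Spaniel, Cocker	Cocker Spaniel
Cross breed	Crossbreed
X breed	Crossbreed
Labradoodle	Labradoodle
Cockapoo	Cockapoo
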