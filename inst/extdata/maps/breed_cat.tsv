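DSH	Domestic Short Hair
Domestic shorthair	Domestic Short Hair
Domestic short hair	Domestic Short Hair
DLH	Domestic Long Hair
Domestic longhair	Domestic Long Hair
British blue	British Blue
Maine coon	Maine Coon
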