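format-version: 1.2
remark: seven-term muscle-tone fixture ontology for the query-expansion worked example

[Term]
id: HP:0000118
name: Phenotypic abnormality

[Term]
id: HP:0003808
name: Abnormal muscle tone
is_a: HP:0000118 ! Phenotypic abnormality

[Term]
id: HP:0001276
name: Hypertonia
is_a: HP:0003808 ! Abnormal muscle tone

[Term]
id: HP:0001252
name: Hypotonia
is_a: HP:0003808 ! Abnormal muscle tone

[Term]
id: HP:0001257
name: Spasticity
is_a: HP:0001276 ! Hypertonia

[Term]
id: HP:0002509
name: Limb hypertonia
is_a: HP:0001276 ! Hypertonia

[Term]
id: HP:0006895
name: Lower limb hypertonia
is_a: HP:0002509 ! Limb hypertonia
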