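# label: Minamata disease (diagnosed, Minamata area; synthetic frequencies)
# n_patients: 269
symptom_label	term_id	frequency
Sensory disturbance	HP:0003474	0.3662
Ataxia	HP:0001251	0.4958
Constriction of visual field	HP:0001133	0.3928
Hearing impairment	HP:0000365	0.1294
Dysarthria	HP:0001260	0.3784
Tremor	HP:0001337	0.5775
Muscle weakness	HP:0001324	0.1693
Headache	HP:0002315	0.1619
Vertigo	HP:0002321	0.1881
Seizure	HP:0001250	0.7223
Memory impairment	HP:0002354	0.5917
Irritability	HP:0000737	0.5339
Insomnia	HP:0100785	0.262
Fatigue	HP:0012378	0.1439
Dysphagia	HP:0002015	0.5681
Excessive salivation	HP:0003781	0.2592
Gait disturbance	HP:0001288	0.1964
Numbness of extremities	HP:0003401	0.5754
Visual impairment	HP:0000505	0.5119
Tinnitus	HP:0000360	0.1461
Joint pain	HP:0002829	0.2417
Back pain	HP:0003418	0.2619
Muscle cramps	HP:0003394	0.7264
Hyporeflexia	HP:0001265	0.6481
Hyperreflexia	HP:0001347	0.529
Intention tremor	HP:0002080	0.1655
Bradykinesia	HP:0002067	0.2679
Postural instability	HP:0002172	0.5078
Mental retardation	HP:0001249	0.0037
Spasticity	HP:0001257	0.2541
Hypotonia	HP:0001252	0.1247
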