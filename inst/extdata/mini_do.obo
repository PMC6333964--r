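format-version: 1.2
data-version: mini-snapshot
remark: Hand-assembled miniature Disease Ontology snapshot for testing and examples. Term identifiers and names follow the real ontology; the hierarchy is heavily pruned.
ontology: doid

[Term]
id: DOID:4
name: disease

[Term]
id: DOID:7
name: disease of anatomical entity
is_a: DOID:4 ! disease

[Term]
id: DOID:14566
name: disease of cellular proliferation
is_a: DOID:4 ! disease

[Term]
id: DOID:0050117
name: disease by infectious agent
is_a: DOID:4 ! disease

[Term]
id: DOID:0014667
name: disease of metabolism
is_a: DOID:4 ! disease

[Term]
id: DOID:162
name: cancer
synonym: "malignant tumor" EXACT []
is_a: DOID:14566 ! disease of cellular proliferation

[Term]
id: DOID:0050686
name: organ system cancer
is_a: DOID:162 ! cancer

[Term]
id: DOID:193
name: reproductive organ cancer
is_a: DOID:0050686 ! organ system cancer

[Term]
id: DOID:3856
name: male reproductive organ cancer
is_a: DOID:193 ! reproductive organ cancer

[Term]
id: DOID:10283
name: prostate cancer
synonym: "prostate carcinoma" EXACT []
synonym: "prostatic cancer" EXACT []
is_a: DOID:3856 ! male reproductive organ cancer

[Term]
id: DOID:1612
name: breast cancer
synonym: "breast carcinoma" RELATED []
is_a: DOID:0050686 ! organ system cancer

[Term]
id: DOID:1324
name: lung cancer
synonym: "lung neoplasm" RELATED []
is_a: DOID:0050686 ! organ system cancer
is_a: DOID:1579 ! respiratory system disease

[Term]
id: DOID:934
name: viral infectious disease
is_a: DOID:0050117 ! disease by infectious agent

[Term]
id: DOID:8469
name: influenza
synonym: "flu" EXACT []
is_a: DOID:934 ! viral infectious disease

[Term]
id: DOID:0050211
name: swine influenza
is_a: DOID:8469 ! influenza

[Term]
id: DOID:2945
name: severe acute respiratory syndrome
synonym: "SARS" EXACT []
is_a: DOID:934 ! viral infectious disease

[Term]
id: DOID:104
name: bacterial infectious disease
is_a: DOID:0050117 ! disease by infectious agent

[Term]
id: DOID:399
name: tuberculosis
synonym: "TB" EXACT []
is_a: DOID:104 ! bacterial infectious disease

[Term]
id: DOID:9351
name: diabetes mellitus
is_a: DOID:0014667 ! disease of metabolism

[Term]
id: DOID:863
name: nervous system disease
is_a: DOID:7 ! disease of anatomical entity

[Term]
id: DOID:10652
name: Alzheimer's disease
synonym: "Alzheimers disease" EXACT []
is_a: DOID:863 ! nervous system disease

[Term]
id: DOID:14330
name: Parkinson's disease
is_a: DOID:863 ! nervous system disease

[Term]
id: DOID:1579
name: respiratory system disease
is_a: DOID:7 ! disease of anatomical entity

[Term]
id: DOID:2841
name: asthma
synonym: "bronchial asthma" EXACT []
is_a: DOID:1579 ! respiratory system disease

[Term]
id: DOID:635
name: acquired immunodeficiency syndrome
synonym: "AIDS" EXACT []
is_a: DOID:934 ! viral infectious disease

[Term]
id: DOID:4325
name: obsolete Ebola hemorrhagic fever
is_obsolete: true
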