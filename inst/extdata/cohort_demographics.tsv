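label	value	percent
male	61	65
female	33	35
age_onset_median_months	24	NA
family_history	25	27
term_birth	83	88
premature_birth	11	12
ASD	36	38
ID	39	42
GDD	13	14
SLD	6	6
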