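# Synthetic actionability snapshot in the OncoKB level schema (gene,
# alteration_type, alteration, level). Illustrative lookup for tests and
# examples; NOT OncoKB data. "any" in the alteration column is a wildcard.
gene	alteration_type	alteration	level
BRCA1	mutation	any	1
BRCA2	mutation	any	1
PIK3CA	mutation	H1047R	3a
PIK3CA	mutation	any	3b
ERBB2	amplification	any	3b
AKT1	mutation	E17K	3a
PTEN	mutation	any	4
PTEN	deletion	any	4
FGFR2	amplification	any	4
NTRK3	fusion	any	1
CDKN2A	deletion	any	4
EGFR	amplification	any	3b
MYC	amplification	any	none
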