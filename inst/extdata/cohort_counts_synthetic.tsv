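# Synthetic per-gene mutated-sample counts for three cohorts, shaped like
# a cross-population comparison of TNBC driver genes (cohort sizes in the
# header comment): AA n=462, CHN n=279, NHW n=626. Counts are round-number
# stand-ins for testing the frequency-comparison machinery only.
gene	AA	CHN	NHW
TP53	437	218	470
PIK3CA	25	53	94
NOTCH1	31	6	25
RB1	31	17	38
KMT2D	27	15	35
PTEN	24	16	33
BRCA1	22	13	29
RYR2	15	20	50
USH2A	13	3	50
GATA3	10	7	14
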