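# Synthetic default gene panel: 36 recurrently mutated myeloid genes.
# Chromosome assignments are approximately real; positions are synthetic
# single-point anchors used only to intersect simulated mutations with
# simulated copy-number segments.  freq = per-patient marginal mutation
# frequency emulated by the cohort generator; dominant_share = fraction of
# that gene's mutations expected in the dominant (ancestral) clone.
gene	chrom	pos	freq	dominant_share
TET2	4	106000000	0.27	0.60
SF3B1	2	198000000	0.23	0.85
ASXL1	20	31000000	0.19	0.35
SRSF2	17	74700000	0.14	0.65
DNMT3A	2	25400000	0.11	0.70
U2AF1	21	44500000	0.09	0.75
ZRSR2	X	15800000	0.08	0.55
RUNX1	21	36100000	0.08	0.50
TP53	17	7570000	0.07	0.75
EZH2	7	148500000	0.07	0.50
STAG2	X	123000000	0.07	0.50
BCOR	X	39900000	0.05	0.50
IDH2	15	90600000	0.04	0.65
CBL	11	119000000	0.04	0.30
JAK2	9	5000000	0.04	0.35
NRAS	1	115200000	0.03	0.40
ETV6	12	11800000	0.025	0.50
IDH1	2	209100000	0.02	0.55
KRAS	12	25400000	0.02	0.30
BCORL1	X	129100000	0.02	0.50
PHF6	X	133500000	0.02	0.50
FLT3	13	28600000	0.015	0.35
NPM1	5	170800000	0.015	0.45
SETBP1	18	42300000	0.015	0.50
GNB1	1	1720000	0.01	0.50
CEBPA	19	33800000	0.01	0.50
GATA2	3	128200000	0.01	0.55
WT1	11	32400000	0.01	0.45
PTPN11	12	112900000	0.01	0.40
RAD21	8	117850000	0.01	0.50
NF1	17	29400000	0.01	0.45
MPL	1	43800000	0.005	0.50
CALR	19	13000000	0.005	0.50
CSF3R	1	36900000	0.005	0.50
KIT	4	55600000	0.005	0.50
SMC3	10	112300000	0.005	0.50
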