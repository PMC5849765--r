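# Synthetic literature-assembled stability constant table for Gd(III) chelation
# speciation under physiological conditions. Cumulative formation constants
# (log10 beta, molar scale, 25 degC, I = 0.1 M unless flagged). Hydroxide
# species are encoded with negative proton stoichiometry; pKw is table-level.
# Values are selected from published compilations and primary determinations;
# where compilations disagree, a value within the published spread was selected
# once (see provenance column). This file is a constructed stand-in assembled
# for simulation, not a transcription of any single published table.
#! pKw 13.78
#! component H charge=1 kind=proton
#! component Gd charge=3 kind=metal
#! component Ca charge=2 kind=metal
#! component Zn charge=2 kind=metal
#! component phosphate charge=-3 kind=endogenous_ligand
#! component carbonate charge=-2 kind=endogenous_ligand
#! component oxalate charge=-2 kind=endogenous_ligand
#! component lactate charge=-1 kind=endogenous_ligand
#! component citrate charge=-3 kind=endogenous_ligand
#! component HOPO charge=-4 kind=synthetic_chelator
#! component DTPA charge=-5 kind=synthetic_chelator
#! component DOTA charge=-4 kind=synthetic_chelator
#! component DTPABMA charge=-3 kind=synthetic_chelator
#! component EDTA charge=-4 kind=synthetic_chelator
label	log_beta	H	Gd	Ca	Zn	phosphate	carbonate	oxalate	lactate	citrate	HOPO	DTPA	DOTA	DTPABMA	EDTA	provenance
OH	-13.78	-1	0	0	0	0	0	0	0	0	0	0	0	0	0	water autoionization, I=0.1
HPO4	11.74	1	0	0	0	1	0	0	0	0	0	0	0	0	0	compilation
H2PO4	18.46	2	0	0	0	1	0	0	0	0	0	0	0	0	0	compilation
H3PO4	20.46	3	0	0	0	1	0	0	0	0	0	0	0	0	0	compilation
HCO3	9.93	1	0	0	0	0	1	0	0	0	0	0	0	0	0	compilation
H2CO3	16.09	2	0	0	0	0	1	0	0	0	0	0	0	0	0	compilation (CO2(aq)+H2CO3)
Hoxa	3.82	1	0	0	0	0	0	1	0	0	0	0	0	0	0	compilation
H2oxa	4.86	2	0	0	0	0	0	1	0	0	0	0	0	0	0	compilation
Hlac	3.66	1	0	0	0	0	0	0	1	0	0	0	0	0	0	compilation
Hcit	5.69	1	0	0	0	0	0	0	0	1	0	0	0	0	0	compilation
H2cit	10.04	2	0	0	0	0	0	0	0	1	0	0	0	0	0	compilation
H3cit	12.91	3	0	0	0	0	0	0	0	1	0	0	0	0	0	compilation
H-HOPO	6.64	1	0	0	0	0	0	0	0	0	1	0	0	0	0	primary determination (highest pKa 6.6)
H2-HOPO	12.52	2	0	0	0	0	0	0	0	0	1	0	0	0	0	primary determination
H3-HOPO	17.34	3	0	0	0	0	0	0	0	0	1	0	0	0	0	primary determination
H4-HOPO	21.00	4	0	0	0	0	0	0	0	0	1	0	0	0	0	primary determination
H-DTPA	10.41	1	0	0	0	0	0	0	0	0	0	1	0	0	0	compilation (highest pKa 10.4)
H2-DTPA	19.01	2	0	0	0	0	0	0	0	0	0	1	0	0	0	compilation; selected within published spread
H3-DTPA	23.10	3	0	0	0	0	0	0	0	0	0	1	0	0	0	compilation
H4-DTPA	25.61	4	0	0	0	0	0	0	0	0	0	1	0	0	0	compilation
H5-DTPA	27.65	5	0	0	0	0	0	0	0	0	0	1	0	0	0	compilation
H-DOTA	11.20	1	0	0	0	0	0	0	0	0	0	0	1	0	0	primary determination (highest pKa 11.2)
H2-DOTA	20.88	2	0	0	0	0	0	0	0	0	0	0	1	0	0	compilation
H3-DOTA	25.43	3	0	0	0	0	0	0	0	0	0	0	1	0	0	compilation
H4-DOTA	29.56	4	0	0	0	0	0	0	0	0	0	0	1	0	0	compilation
H-BMA	9.37	1	0	0	0	0	0	0	0	0	0	0	0	1	0	primary determination
H2-BMA	13.75	2	0	0	0	0	0	0	0	0	0	0	0	1	0	primary determination
H3-BMA	17.06	3	0	0	0	0	0	0	0	0	0	0	0	1	0	primary determination
H4-BMA	18.49	4	0	0	0	0	0	0	0	0	0	0	0	1	0	primary determination
H-EDTA	10.19	1	0	0	0	0	0	0	0	0	0	0	0	0	1	compilation
H2-EDTA	16.32	2	0	0	0	0	0	0	0	0	0	0	0	0	1	compilation
H3-EDTA	19.01	3	0	0	0	0	0	0	0	0	0	0	0	0	1	compilation
H4-EDTA	21.01	4	0	0	0	0	0	0	0	0	0	0	0	0	1	compilation
GdOH	-8.30	-1	1	0	0	0	0	0	0	0	0	0	0	0	0	hydrolysis compilation; selected within published spread
GdCO3	6.00	0	1	0	0	0	1	0	0	0	0	0	0	0	0	lanthanide carbonate compilation
Gd(CO3)2	10.70	0	1	0	0	0	2	0	0	0	0	0	0	0	0	lanthanide carbonate compilation
GdHPO4	16.94	1	1	0	0	1	0	0	0	0	0	0	0	0	0	lanthanide phosphate compilation
Gdoxa	4.90	0	1	0	0	0	0	1	0	0	0	0	0	0	0	compilation
Gd(oxa)2	8.70	0	1	0	0	0	0	2	0	0	0	0	0	0	0	compilation
Gdlac	2.60	0	1	0	0	0	0	0	1	0	0	0	0	0	0	compilation
Gd(lac)2	4.60	0	1	0	0	0	0	0	2	0	0	0	0	0	0	compilation
Gdcit	7.60	0	1	0	0	0	0	0	0	1	0	0	0	0	0	lanthanide citrate compilation
GdHcit	10.40	1	1	0	0	0	0	0	0	1	0	0	0	0	0	estimated from protonation of Gdcit
Gd(cit)2	11.60	0	1	0	0	0	0	0	0	2	0	0	0	0	0	lanthanide citrate compilation
Gd-HOPO	20.50	0	1	0	0	0	0	0	0	0	1	0	0	0	0	anchored to published pH 7.4 conditional value 20.5(1)
Gd-DTPA	22.46	0	1	0	0	0	0	0	0	0	0	1	0	0	0	primary determination
GdH-DTPA	24.46	1	1	0	0	0	0	0	0	0	0	1	0	0	0	protonated complex, estimated log K_H = 2.0
Gd-DOTA	24.20	0	1	0	0	0	0	0	0	0	0	0	1	0	0	compilation; selected within published spread 24.0-25.3
Gd-BMA	16.85	0	1	0	0	0	0	0	0	0	0	0	0	1	0	primary determination
Gd-EDTA	17.70	0	1	0	0	0	0	0	0	0	0	0	0	0	1	compilation; selected within published spread
CaCO3	3.22	0	0	1	0	0	1	0	0	0	0	0	0	0	0	compilation
CaHCO3	11.37	1	0	1	0	0	1	0	0	0	0	0	0	0	0	compilation
CaHPO4	14.44	1	0	1	0	1	0	0	0	0	0	0	0	0	0	compilation
Caoxa	3.00	0	0	1	0	0	0	1	0	0	0	0	0	0	0	compilation
Calac	1.45	0	0	1	0	0	0	0	1	0	0	0	0	0	0	compilation
Cacit	4.87	0	0	1	0	0	0	0	0	1	0	0	0	0	0	compilation
CaHcit	8.69	1	0	1	0	0	0	0	0	1	0	0	0	0	0	compilation
Ca-DTPA	10.75	0	0	1	0	0	0	0	0	0	0	1	0	0	0	primary determination
CaH-DTPA	16.86	1	0	1	0	0	0	0	0	0	0	1	0	0	0	protonated complex, log K_H = 6.11
Ca-DOTA	17.23	0	0	1	0	0	0	0	0	0	0	0	1	0	0	primary determination
Ca-BMA	7.17	0	0	1	0	0	0	0	0	0	0	0	0	1	0	primary determination
Ca-EDTA	10.61	0	0	1	0	0	0	0	0	0	0	0	0	0	1	compilation
ZnOH	-8.78	-1	0	0	1	0	0	0	0	0	0	0	0	0	0	hydrolysis compilation
Zn(OH)2	-16.46	-2	0	0	1	0	0	0	0	0	0	0	0	0	0	hydrolysis compilation
ZnCO3	4.76	0	0	0	1	0	1	0	0	0	0	0	0	0	0	compilation
ZnHCO3	11.33	1	0	0	1	0	1	0	0	0	0	0	0	0	0	compilation
ZnHPO4	15.04	1	0	0	1	1	0	0	0	0	0	0	0	0	0	compilation
Znoxa	3.88	0	0	0	1	0	0	1	0	0	0	0	0	0	0	compilation
Zn(oxa)2	6.40	0	0	0	1	0	0	2	0	0	0	0	0	0	0	compilation
Znlac	1.86	0	0	0	1	0	0	0	1	0	0	0	0	0	0	compilation
Zncit	4.98	0	0	0	1	0	0	0	0	1	0	0	0	0	0	compilation
ZnHcit	8.67	1	0	0	1	0	0	0	0	1	0	0	0	0	0	compilation
Zn-DTPA	18.29	0	0	0	1	0	0	0	0	0	0	1	0	0	0	primary determination
ZnH-DTPA	23.89	1	0	0	1	0	0	0	0	0	0	1	0	0	0	protonated complex, log K_H = 5.6
Zn-DOTA	18.70	0	0	0	1	0	0	0	0	0	0	0	1	0	0	compilation
Zn-BMA	12.04	0	0	0	1	0	0	0	0	0	0	0	0	1	0	primary determination
Zn-EDTA	16.50	0	0	0	1	0	0	0	0	0	0	0	0	0	1	compilation
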