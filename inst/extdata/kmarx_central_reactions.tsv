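id	metacyc_id	index	equation	reversible	lb	ub
GPD	1.1.1.8-RXN	1	DHAP + NADH -> G3P + NAD	FALSE	0	inf
TKT1	1TRANSKETO-RXN	2	R5P + X5P <-> GAP + S7P	TRUE	-inf	inf
OGDH	2OXOGLUTARATEDEH-RXN	3	AKG + NAD + COA -> SUCCOA + NADH + CO2	FALSE	0	inf
ENO	2PGADEHYDRAT-RXN	4	PG2 <-> PEP + H2O	TRUE	-inf	inf
TKT2	2TRANSKETO-RXN	5	X5P + E4P <-> F6P + GAP	TRUE	-inf	inf
PGM	3PGAREARR-RXN	6	PG3 <-> PG2	TRUE	-inf	inf
PFK	6PFRUCTPHOS-RXN	7	F6P + ATP -> F16BP + ADP	FALSE	0	inf
GND	6PGLUCONDEHYDROG-RXN	8	PG6 + NADP -> RU5P + NADPH + CO2	FALSE	0	inf
SOL	6PGLUCONOLACT-RXN	9	GL6P + H2O -> PG6	FALSE	0	inf
ACS	ACETATE--COA-LIGASE-RXN	10	AC + 2 ATP + COA -> ACCOA + 2 PI + 2 ADP	FALSE	0	inf
ACO1	ACONITATEDEHYDR-RXN	11	CIT <-> ACON + H2O	TRUE	-inf	inf
ACO2	ACONITATEHYDR-RXN	12	ACON + H2O <-> ICIT	TRUE	-inf	inf
FAA	ACYLCOASYN-RXN	13	FFA + 2 ATP + COA -> FACOA + 2 PI + 2 ADP	FALSE	0	inf
ADH	ALCOHOL-DEHYDROG-RXN	14	ACALD + NADH <-> ETOH + NAD	TRUE	-inf	inf
CS	CITSYN-RXN	15	ACCOA + OAA + H2O -> CIT + COA	FALSE	0	inf
XDH	D-XYLULOSE-REDUCTASE-RXN	16	XYLT + NAD <-> XYLU + NADH	TRUE	-inf	inf
ECH	ENOYL-COA-HYDRAT-RXN	17	ENOCOA + H2O <-> HACOA	TRUE	-inf	inf
FBA	F16ALDOLASE-RXN	18	F16BP <-> DHAP + GAP	TRUE	-inf	inf
FBP	F16BDEPHOS-RXN	19	F16BP + H2O -> F6P + PI	FALSE	0	inf
FUMH	FUMHYDR-RXN	20	FUM + H2O <-> MAL	TRUE	-inf	inf
GAPDH	GAPOXNPHOSPHN-RXN	21	GAP + PI + NAD <-> BPG + NADH	TRUE	-inf	inf
G6PDH	GLU6PDEHYDROG-RXN	22	G6P + NADP -> GL6P + NADPH	FALSE	0	inf
GLK	GLUCOKIN-RXN	23	GLC + ATP -> G6P + ADP	FALSE	0	inf
GPP	GLYCEROL-1-PHOSPHATASE-RXN	24	G3P + H2O -> GLYC + PI	FALSE	0	inf
ICL	ISOCIT-CLEAV-RXN	25	ICIT -> SUC + GLX	FALSE	0	inf
IDP	ISOCITDEH-RXN	26	ICIT + NADP -> AKG + NADPH + CO2	FALSE	0	inf
IDH	ISOCITRATE-DEHYDROGENASE-NAD+-RXN	27	ICIT + NAD -> AKG + NADH + CO2	FALSE	0	inf
KAT	KETOACYLCOATHIOL-RXN	28	KACOA + COA -> 2 ACCOA	FALSE	0	inf
MDH	MALATE-DEH-RXN	29	MAL + NAD <-> OAA + NADH	TRUE	-inf	inf
MAE	MALIC-NADP-RXN	30	MAL + NADP -> PYR + NADPH + CO2	FALSE	0	inf
MLS	MALSYN-RXN	31	ACCOA + GLX + H2O -> MAL + COA	FALSE	0	inf
HADH	OHACYL-COA-DEHYDROG-RXN	32	HACOA + NAD <-> KACOA + NADH	TRUE	-inf	inf
PPC	PEPCARBOX-RXN	33	PEP + CO2 + H2O -> OAA + PI	FALSE	0	inf
PCK	PEPCARBOXYKIN-RXN	34	OAA + ATP -> PEP + ADP + CO2	FALSE	0	inf
PYK	PEPDEPHOS-RXN	35	PEP + ADP -> PYR + ATP	FALSE	0	inf
PPS	PEPSYNTH-RXN	36	PYR + 2 ATP + H2O -> PEP + PI + 2 ADP	FALSE	0	inf
PGI	PGLUCISOM-RXN	37	G6P <-> F6P	TRUE	-inf	inf
PGK	PHOSGLYPHOS-RXN	38	BPG + ADP <-> PG3 + ATP	TRUE	-inf	inf
PYC	PYRUVATE-CARBOXYLASE-RXN	39	PYR + ATP + CO2 + H2O -> OAA + PI + ADP	FALSE	0	inf
RKI	RIB5PISOM-RXN	40	RU5P <-> R5P	TRUE	-inf	inf
RPE	RIBULP3EPIM-RXN	41	RU5P <-> X5P	TRUE	-inf	inf
PDH_E3	RXN0-1132	42	DHLPAM + NAD -> LPAM + NADH	FALSE	0	inf
PDH_E2	RXN0-1133	43	ACLPAM + COA -> ACCOA + DHLPAM	FALSE	0	inf
PDH_E1	RXN0-1134	44	PYR + LPAM -> ACLPAM + CO2	FALSE	0	inf
POX	RXN-11026	45	FACOA + 0.5 O2 -> ENOCOA + H2O	FALSE	0	inf
PDC	RXN-6161	46	PYR -> ACALD + CO2	FALSE	0	inf
ALD	RXN66-3	47	ACALD + NAD + H2O -> AC + NADH	FALSE	0	inf
XR	RXN-8773	48	XYL + NADPH -> XYLT + NADP	FALSE	0	inf
SCS	SUCCCOASYN-RXN	49	SUCCOA + PI + ADP <-> SUC + ATP + COA	TRUE	-inf	inf
SDH	SUCCINATE-DEHYDROGENASE-UBIQUINONE-RXN	50	SUC + 1.5 PI + 1.5 ADP + 0.5 O2 -> FUM + 1.5 ATP + H2O	FALSE	0	inf
TAL	TRANSALDOL-RXN	51	GAP + S7P <-> F6P + E4P	TRUE	-inf	inf
TPI	TRIOSEPISOMERIZATION-RXN	52	DHAP <-> GAP	TRUE	-inf	inf
vETC	vETC	53	2.5 PI + 2.5 ADP + NADH + 0.5 O2 -> 2.5 ATP + NAD + H2O	FALSE	0	inf
vEtAc	vEthylAcetate	54	ETOH + ACCOA -> ETAC + COA	FALSE	0	inf
vGrowth	vGrowth	55	0.276 G6P + 0.129 GAP + 1.496 PG3 + 0.519 PEP + 2.833 PYR + 3.748 ACCOA + 1.079 AKG + 1.787 OAA + 0.898 R5P + 0.361 E4P + 41.7 ATP + 3.547 NAD + 16 NADPH -> 41.7 PI + 41.7 ADP + 3.547 NADH + 16 NADP + 3.748 COA + BIOMASS	FALSE	0	inf
XKS	XYLULOKIN-RXN	56	XYLU + ATP -> X5P + ADP	FALSE	0	inf
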