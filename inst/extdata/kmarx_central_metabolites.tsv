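id	name	is_cofactor	default_exchangeable
GLC	D-glucose	FALSE	TRUE
XYL	D-xylose	FALSE	TRUE
G6P	glucose-6-phosphate	FALSE	FALSE
F6P	fructose-6-phosphate	FALSE	FALSE
F16BP	fructose-1,6-bisphosphate	FALSE	FALSE
DHAP	dihydroxyacetone phosphate	FALSE	FALSE
GAP	glyceraldehyde-3-phosphate	FALSE	FALSE
BPG	1,3-bisphosphoglycerate	FALSE	FALSE
PG3	3-phosphoglycerate	FALSE	FALSE
PG2	2-phosphoglycerate	FALSE	FALSE
PEP	phosphoenolpyruvate	FALSE	FALSE
PYR	pyruvate	FALSE	FALSE
ACALD	acetaldehyde	FALSE	FALSE
ETOH	ethanol	FALSE	TRUE
AC	acetate	FALSE	TRUE
ACCOA	acetyl-CoA	FALSE	FALSE
ETAC	ethyl acetate	FALSE	TRUE
CIT	citrate	FALSE	FALSE
ACON	cis-aconitate	FALSE	FALSE
ICIT	isocitrate	FALSE	FALSE
AKG	2-oxoglutarate	FALSE	FALSE
SUCCOA	succinyl-CoA	FALSE	FALSE
SUC	succinate	FALSE	FALSE
FUM	fumarate	FALSE	FALSE
MAL	malate	FALSE	FALSE
OAA	oxaloacetate	FALSE	FALSE
GLX	glyoxylate	FALSE	FALSE
GL6P	6-phosphogluconolactone	FALSE	FALSE
PG6	6-phosphogluconate	FALSE	FALSE
RU5P	ribulose-5-phosphate	FALSE	FALSE
R5P	ribose-5-phosphate	FALSE	FALSE
X5P	xylulose-5-phosphate	FALSE	FALSE
S7P	sedoheptulose-7-phosphate	FALSE	FALSE
E4P	erythrose-4-phosphate	FALSE	FALSE
XYLT	xylitol	FALSE	TRUE
XYLU	D-xylulose	FALSE	FALSE
G3P	glycerol-3-phosphate	FALSE	FALSE
GLYC	glycerol	FALSE	TRUE
FFA	generic fatty acid	FALSE	TRUE
FACOA	generic fatty acyl-CoA	FALSE	FALSE
ENOCOA	trans-2-enoyl-CoA	FALSE	FALSE
HACOA	3-hydroxyacyl-CoA	FALSE	FALSE
KACOA	3-ketoacyl-CoA	FALSE	FALSE
LPAM	lipoamide (oxidised)	FALSE	FALSE
ACLPAM	S-acetyl-dihydrolipoamide	FALSE	FALSE
DHLPAM	dihydrolipoamide	FALSE	FALSE
PI	orthophosphate	TRUE	TRUE
ATP	ATP	TRUE	FALSE
ADP	ADP	TRUE	FALSE
NAD	NAD+	TRUE	FALSE
NADH	NADH	TRUE	FALSE
NADP	NADP+	TRUE	FALSE
NADPH	NADPH	TRUE	FALSE
COA	coenzyme A	TRUE	FALSE
O2	oxygen	FALSE	TRUE
CO2	carbon dioxide	FALSE	TRUE
H2O	water	FALSE	TRUE
BIOMASS	biomass	FALSE	TRUE
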