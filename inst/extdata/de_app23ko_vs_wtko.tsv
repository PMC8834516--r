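id	name	log2fc	confidence
GNAI3	Guanine nucleotide-binding protein G(k) subunit alpha	3.55	0.56
MACF1	Microtubule-actin crosslinking factor 1	3.46	0.57
FN3K	Fructosamine-3-kinase	3.18	0.78
THIKA	3-ketoacyl-CoA thiolase A, peroxisomal	3.08	0.62
SYMC	Methionine-tRNA ligase, cytoplasmic	3.06	0.62
CPSF6	Cleavage and polyadenylation specificity factor subunit 6	2.75	0.62
NFU1	NFU1 iron-sulfur cluster scaffold homolog, mitochondrial	2.45	0.58
ESYT1	Extended synaptotagmin-1	2.40	0.71
ENOG	Gamma-enolase	2.07	0.60
SEP6	Septin-6	1.62	0.60
CLPP	ATP-dependent Clp protease proteolytic subunit, mitochondrial	1.49	0.88
A4	Amyloid beta A4 protein	1.26	0.62
NCLN	Nicalin	0.92	0.55
UCRI	Cytochrome b-c1 complex subunit Rieske, mitochondrial	0.83	0.59
NFM	Neurofilament medium polypeptide	0.73	0.79
UBE2N	Ubiquitin-conjugating enzyme E2 N	0.68	0.65
KPCG	Protein kinase C gamma type	0.58	0.67
CAMP2	Calmodulin-regulated spectrin-associated protein 2	0.50	0.56
APOD	Apolipoprotein D	0.49	0.56
BRSK1	Serine/threonine-protein kinase BRSK1	0.46	0.67
SCPDL	Saccharopine dehydrogenase-like oxidoreductase	0.39	0.68
TNPO1	Transportin-1	0.36	0.56
GLU2B	Glucosidase 2 subunit beta	0.16	0.60
STMN1	Stathmin	-0.25	0.63
GPM6A	Neuronal membrane glycoprotein M6-a	-0.30	0.57
MPP2	MAGUK p55 subfamily member 2	-0.36	0.63
NEUG	Neurogranin	-0.49	0.68
OTU6B	OTU domain-containing protein 6B	-0.49	0.69
PC4L1	Purkinje cell protein 4-like protein 1	-0.51	0.83
CH10	10 kDa heat shock protein, mitochondrial	-0.56	0.64
HBB1	Hemoglobin subunit beta-1	-0.60	0.71
MDHC	Malate dehydrogenase, cytoplasmic	-0.82	0.57
SNG1	Synaptogyrin-1	-0.92	0.55
KCAB2	Voltage-gated potassium channel subunit beta-2	-0.94	0.66
MAAI	Maleylacetoacetate isomerase	-1.37	0.65
TDRKH	Tudor and KH domain-containing protein	-1.66	0.57
ENOPH	Enolase-phosphatase E1	-2.11	0.60
SARM1	Sterile alpha and TIR motif-containing protein 1	-2.21	0.62
PZP	Pregnancy zone protein	-2.38	0.62
PUR6	Multifunctional protein ADE2	-4.39	0.70
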