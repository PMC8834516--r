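id	name	log2fc	confidence
UCHL1	Ubiquitin carboxyl-terminal hydrolase isozyme L1	6.02	0.58
MATR3	Matrin-3	3.32	0.57
MDHC	Malate dehydrogenase, cytoplasmic	1.78	0.55
MAAI	Maleylacetoacetate isomerase	1.59	0.70
CPLX2	Complexin-2	1.41	0.57
S4A4	Electrogenic sodium bicarbonate cotransporter 1	1.21	0.57
CPLX1	Complexin-1	1.16	0.59
RAB1B	Ras-related protein Rab-1B	1.01	0.71
HBB1	Hemoglobin subunit beta-1	0.77	0.66
NDKB	Nucleoside diphosphate kinase B	0.43	0.72
PPME1	Protein phosphatase methylesterase 1	0.43	0.62
GNAZ	Guanine nucleotide-binding protein G(z) subunit alpha	-0.37	0.55
OGT1	UDP-N-acetylglucosamine-peptide N-acetylglucosaminyltransferase 110 kDa subunit	-0.45	0.55
CLPP	ATP-dependent Clp protease proteolytic subunit, mitochondrial	-0.55	0.63
F210A	Protein FAM210A	-0.56	0.67
RL29	60S ribosomal protein L29	-0.74	0.56
KPCG	Protein kinase C gamma type	-0.94	0.72
PGM2L	Glucose 1,6-bisphosphate synthase	-0.94	0.72
UBE2N	Ubiquitin-conjugating enzyme E2 N	-1.00	0.79
RS9	40S ribosomal protein S9	-1.25	0.77
MECR	Trans-2-enoyl-CoA reductase, mitochondrial	-1.48	0.56
VAT1L	Synaptic vesicle membrane protein VAT-1 homolog-like	-1.49	0.56
RAB3B	Ras-related protein Rab-3B	-1.75	0.55
GUAA	GMP synthase [glutamine-hydrolyzing]	-2.23	0.62
GCYB1	Guanylate cyclase soluble subunit beta-1	-2.39	0.56
GMFB	Glia maturation factor beta	-2.57	0.58
THIKA	3-ketoacyl-CoA thiolase A, peroxisomal	-2.97	0.64
2ABG	Serine/threonine-protein phosphatase 2A 55 kDa regulatory subunit B gamma isoform	-3.43	0.61
MYDGF	Myeloid-derived growth factor	-3.59	0.57
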