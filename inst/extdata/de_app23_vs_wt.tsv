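id	name	log2fc	confidence
ELAV4	ELAV-like protein 4	3.93	0.55
TBCEL	Tubulin-specific chaperone cofactor E-like protein	2.84	0.56
ATP5I	ATP synthase subunit e, mitochondrial	2.56	0.60
GCYB1	Guanylate cyclase soluble subunit beta-1	2.47	0.71
SNX4	Sorting nexin-4	2.34	0.58
PSMD3	26S proteasome non-ATPase regulatory subunit 3	1.31	0.68
A4	Amyloid beta A4 protein	1.18	0.78
CPLX2	Complexin-2	1.09	0.58
CPLX1	Complexin-1	1.08	0.63
RAB1B	Ras-related protein Rab-1B	1.03	0.70
BAG3	BAG family molecular chaperone regulator 3	0.91	0.55
CAH8	Carbonic anhydrase-related protein	0.76	0.67
HBB1	Hemoglobin subunit beta-1	0.70	0.56
ABHGA	Protein ABHD16A	0.60	0.65
CAZA2	F-actin-capping protein subunit alpha-2	0.57	0.65
PRVA	Parvalbumin alpha	0.47	0.68
NFH	Neurofilament heavy polypeptide	0.47	0.67
HNRPU	Heterogeneous nuclear ribonucleoprotein U	0.41	0.55
OCAD2	OCIA domain-containing protein 2	0.38	0.63
L1CAM	Neural cell adhesion molecule L1	0.37	0.60
FA49B	Protein FAM49B	0.33	0.66
IPP2	Protein phosphatase inhibitor 2	0.33	0.63
GNAZ	Guanine nucleotide-binding protein G(z) subunit alpha	0.32	0.56
S4A4	Electrogenic sodium bicarbonate cotransporter 1	0.28	0.56
NEUG	Neurogranin	0.28	0.55
CANB1	Calcineurin subunit B type 1	0.27	0.55
NAC2	Sodium/calcium exchanger 2	-0.48	0.81
MP2K1	Dual specificity mitogen-activated protein kinase kinase 1	-0.49	0.57
NPTXR	Neuronal pentraxin receptor	-0.53	0.55
PC4L1	Purkinje cell protein 4-like protein 1	-0.54	0.82
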