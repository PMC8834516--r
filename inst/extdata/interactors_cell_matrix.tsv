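id	name	p_wt	p_app23	phenotype
HSP72	Heat shock-related 70 kDa protein 2	2.4e-15		WT
ANK1	Ankyrin-1	4.7e-14		WT
FIBG	Fibrinogen gamma chain	1.0e-11		WT
TNIK	Traf2 and NCK-interacting protein kinase	1.5e-07		WT
SRC8	Src substrate cortactin	9.4e-07		WT
LRP1	Prolow-density lipoprotein receptor-related protein 1	2.3e-06		WT
CYLD	Ubiquitin carboxyl-terminal hydrolase CYLD	2.9e-06		WT
CPNE5	Copine-5	4.8e-06		WT
ENPL	Endoplasmin	6.6e-06		WT
CFAH	Complement factor H	2.5e-05		WT
ASTN1	Astrotactin-1	2.6e-05		WT
ACBG1	Long-chain-fatty-acid-CoA ligase ACSBG1	6.9e-05		WT
FAS	Fatty acid synthase	4.2e-04		WT
VATC1	V-type proton ATPase subunit C 1	5.3e-04		WT
IDE	Insulin-degrading enzyme	6.8e-04		WT
K2C1	Keratin, type II cytoskeletal 1	2.9e-03		WT
SPB6	Serpin B6	3.5e-03		WT
ADA10	Disintegrin and metalloproteinase domain-containing protein 10	4.2e-03		WT
INP4A	Type I inositol 3,4-bisphosphate 4-phosphatase	6.9e-03		WT
CYTC	Cystatin-C	7.7e-03		WT
PICAL	Phosphatidylinositol-binding clathrin assembly protein	7.8e-03		WT
HYEP	Epoxide hydrolase 1	8.8e-03		WT
PDIA3	Protein disulfide-isomerase A3	1.0e-02		WT
L2GL1	Lethal(2) giant larvae protein homolog 1	1.0e-02		WT
CUL5	Cullin-5	1.1e-02		WT
HEXB	Beta-hexosaminidase subunit beta	1.5e-02		WT
CKAP5	Cytoskeleton-associated protein 5	1.5e-02		WT
MSRA	Mitochondrial peptide methionine sulfoxide reductase	1.6e-02		WT
APBB1	Amyloid-beta A4 precursor protein-binding family B member 1	2.0e-02		WT
OGT1	UDP-N-acetylglucosamine-peptide N-acetylglucosaminyltransferase 110 kDa subunit	2.0e-02		WT
ARBK1	Beta-adrenergic receptor kinase 1	2.4e-02		WT
ABR	Active breakpoint cluster region-related protein	2.5e-02		WT
RAB21	Ras-related protein Rab-21	2.6e-02		WT
RHEB	GTP-binding protein Rheb	2.7e-02		WT
ITPR1	Inositol 1,4,5-trisphosphate receptor type 1	2.7e-02		WT
WASF1	Wiskott-Aldrich syndrome protein family member 1	2.8e-02		WT
GARS	Glycine-tRNA ligase	3.5e-02		WT
RACK1	Receptor of activated protein C kinase 1	3.5e-02		WT
ACLY	ATP-citrate synthase	3.7e-02		WT
SNAA	Alpha-soluble NSF attachment protein	3.8e-02		WT
ATP5J	ATP synthase-coupling factor 6, mitochondrial	4.0e-02		WT
E41L3	Band 4.1-like protein 3	4.0e-02		WT
SOGA3	Protein SOGA3	4.4e-02		WT
ALDR	Aldose reductase	4.6e-02		WT
LYNX1	Ly-6/neurotoxin-like protein 1	4.8e-02		WT
DAAM1	Disheveled-associated activator of morphogenesis 1	5.1e-12	1.1e-04	WT_APP23
PLAP	Phospholipase A-2-activating protein	3.2e-06	2.6e-03	WT_APP23
APOE	Apolipoprotein E	3.5e-05	4.3e-08	WT_APP23
RIN1	Ras and Rab interactor 1	1.3e-03	2.9e-03	WT_APP23
RIF1	Telomere-associated protein RIF1	9.7e-03	2.8e-02	WT_APP23
NDRG1	Protein NDRG1	1.9e-02	1.0e-16	WT_APP23
SYT2	Synaptotagmin-2	4.2e-02	5.0e-02	WT_APP23
ALBU	Serum albumin	5.5e-02	2.8e-09	WT_APP23
KCRB	Creatine kinase B-type		1.0e-16	APP23
CRYAB	Alpha-crystallin B chain		1.0e-16	APP23
1433F	14-3-3 protein eta		1.0e-16	APP23
LANC2	LanC-like protein 2		2.4e-15	APP23
GDIR1	Rho GDP-dissociation inhibitor 1		6.8e-12	APP23
NRX1A	Neurexin-1		2.1e-11	APP23
CAPS1	Calcium-dependent secretion activator 1		3.7e-11	APP23
VATA	V-type proton ATPase catalytic subunit A		1.4e-09	APP23
EF1A1	Elongation factor 1-alpha 1		3.5e-08	APP23
MBP	Myelin basic protein		3.7e-08	APP23
CADM2	Cell adhesion molecule 2		1.7e-06	APP23
PCAT1	Lysophosphatidylcholine acyltransferase 1		2.3e-06	APP23
NPTX1	Neuronal pentraxin-1		4.0e-06	APP23
LYRIC	Protein LYRIC		4.0e-06	APP23
PP4P1	Type 1 phosphatidylinositol 4,5-bisphosphate 4-phosphatase		5.7e-06	APP23
CAH2	Carbonic anhydrase 2		7.4e-06	APP23
ATPA	ATP synthase subunit alpha, mitochondrial		1.3e-05	APP23
LSAMP	Limbic system-associated membrane protein		1.8e-05	APP23
GLNA	Glutamine synthetase		2.4e-05	APP23
SNP25	Synaptosomal-associated protein 25		3.6e-05	APP23
PDIA6	Protein disulfide-isomerase A6		5.1e-05	APP23
HS71A	Heat shock 70 kDa protein 1A		8.7e-05	APP23
OCRL	Inositol polyphosphate 5-phosphatase OCRL-1		9.2e-05	APP23
KPCB	Protein kinase C beta type		1.0e-04	APP23
VINC	Vinculin		1.1e-04	APP23
AT1B2	Sodium/potassium-transporting ATPase subunit beta-2		1.3e-04	APP23
GNAO	Guanine nucleotide-binding protein G(o) subunit alpha		1.4e-04	APP23
MYH10	Myosin-10		2.5e-04	APP23
CDK5	Cyclin-dependent-like kinase 5		3.0e-04	APP23
KCNC3	Potassium voltage-gated channel subfamily C member 3		3.1e-04	APP23
NCKP1	Nck-associated protein 1		6.6e-04	APP23
S10AD	Protein S100-A13		8.5e-04	APP23
RAB3A	Ras-related protein Rab-3A		9.6e-04	APP23
ADPRH	[Protein ADP-ribosylarginine] hydrolase		1.1e-03	APP23
DYN1	Dynamin-1		1.4e-03	APP23
SYT1	Synaptotagmin-1		1.7e-03	APP23
PPP5	Serine/threonine-protein phosphatase 5		2.3e-03	APP23
ENAH	Protein enabled homolog		2.4e-03	APP23
RAP2B	Ras-related protein Rap-2b		3.2e-03	APP23
KPCG	Protein kinase C gamma type		3.4e-03	APP23
SH3G1	Endophilin-A2		3.5e-03	APP23
MK03	Mitogen-activated protein kinase 3		4.2e-03	APP23
PGK1	Phosphoglycerate kinase 1		4.6e-03	APP23
GNAZ	Guanine nucleotide-binding protein G(z) subunit alpha		5.2e-03	APP23
ANXA5	Annexin A5		6.8e-03	APP23
GNB5	Guanine nucleotide-binding protein subunit beta-5		9.6e-03	APP23
E41L1	Band 4.1-like protein 1		1.1e-02	APP23
UCHL1	Ubiquitin carboxyl-terminal hydrolase isozyme L1		1.1e-02	APP23
VATB2	V-type proton ATPase subunit B, brain isoform		1.2e-02	APP23
GNAI2	Guanine nucleotide-binding protein G(i) subunit alpha-2		1.2e-02	APP23
CAP2	Adenylyl cyclase-associated protein 2		1.2e-02	APP23
DPYL2	Dihydropyrimidinase-related protein 2		1.5e-02	APP23
RAB14	Ras-related protein Rab-14		1.5e-02	APP23
PP2BA	Serine/threonine-protein phosphatase 2B catalytic subunit alpha isoform		1.7e-02	APP23
HCN1	Potassium/sodium hyperpolarization-activated cyclic nucleotide-gated channel 1		1.8e-02	APP23
PRAF3	PRA1 family protein 3		1.8e-02	APP23
SPTN1	Spectrin alpha chain, non-erythrocytic 1		2.0e-02	APP23
GRIA2	Glutamate receptor 2		3.3e-02	APP23
SAHH2	S-adenosylhomocysteine hydrolase-like protein 1		3.8e-02	APP23
COR1C	Coronin-1C		4.2e-02	APP23
ENOG	Gamma-enolase		4.3e-02	APP23
AT1A1	Sodium/potassium-transporting ATPase subunit alpha-1		4.7e-02	APP23
NSF1C	NSFL1 cofactor p47		5.0e-02	APP23
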