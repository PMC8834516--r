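id	name	log2fc	confidence
CPSF6	Cleavage and polyadenylation specificity factor subunit 6	3.76	0.68
GNAI3	Guanine nucleotide-binding protein G(k) subunit alpha	3.75	0.55
PADI2	Protein-arginine deiminase type-2	3.59	0.59
TOLIP	Toll-interacting protein	3.53	0.61
SYMC	Methionine-tRNA ligase, cytoplasmic	3.46	0.60
ECHD1	Ethylmalonyl-CoA decarboxylase	2.54	0.60
HSDL1	Inactive hydroxysteroid dehydrogenase-like protein 1	2.50	0.55
AGRB1	Brain-specific angiogenesis inhibitor 1	2.49	0.55
NFU1	NFU1 iron-sulfur cluster scaffold homolog, mitochondrial	2.21	0.66
FBX41	F-box only protein 41	1.17	0.64
APOD	Apolipoprotein D	0.68	0.57
SNAA	Alpha-soluble NSF attachment protein	0.47	0.58
HEBP1	Heme-binding protein 1	0.27	0.56
RRAGC	Ras-related GTP-binding protein C	0.27	0.55
DTD1	D-tyrosyl-tRNA(Tyr) deacylase 1	0.23	0.68
RL6	60S ribosomal protein L6	0.21	0.56
CORO7	Coronin-7	-0.29	0.63
AN32A	Acidic leucine-rich nuclear phosphoprotein 32 family member A	-0.35	0.64
HNRPU	Heterogeneous nuclear ribonucleoprotein U	-0.43	0.73
CAH8	Carbonic anhydrase-related protein	-0.47	0.55
MBP	Myelin basic protein	-0.61	0.75
HBB1	Hemoglobin subunit beta-1	-0.62	0.79
MYEF2	Myelin expression factor 2	-0.63	0.57
S20A2	Sodium-dependent phosphate transporter 2	-0.79	0.80
KCAB2	Voltage-gated potassium channel subunit beta-2	-0.85	0.61
RL35A	60S ribosomal protein L35a	-0.94	0.55
RS28	40S ribosomal protein S28	-1.01	0.67
LSM6	U6 snRNA-associated Sm-like protein LSm6	-1.02	0.57
RL29	60S ribosomal protein L29	-1.03	0.78
AN32E	Acidic leucine-rich nuclear phosphoprotein 32 family member E	-1.03	0.61
RS9	40S ribosomal protein S9	-1.16	0.61
SNG1	Synaptogyrin-1	-1.23	0.57
SARM1	Sterile alpha and TIR motif-containing protein 1	-2.27	0.65
EXOG	Nuclease EXOG, mitochondrial	-3.22	0.56
RHG23	Rho GTPase-activating protein 23	-3.38	0.63
ROCK2	Rho-associated protein kinase 2	-3.61	0.61
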