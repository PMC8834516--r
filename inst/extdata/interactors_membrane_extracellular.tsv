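id	name	p_wt	p_app23	phenotype
TENR	Tenascin-R	1.5e-04		WT
PTPRD	Receptor-type tyrosine-protein phosphatase delta	3.1e-03		WT
RSU1	Ras suppressor protein 1	4.7e-03		WT
CAD12	Cadherin-12	6.4e-03		WT
NRCAM	Neuronal cell adhesion molecule	9.6e-03		WT
S12A5	Solute carrier family 12 member 5	1.9e-02		WT
SCN9A	Sodium channel protein type 9 subunit alpha	3.8e-02		WT
SC6A1	Sodium- and chloride-dependent GABA transporter 1	2.9e-02	8.0e-03	WT_APP23
L1CAM	Neural cell adhesion molecule L1	3.2e-02	2.4e-02	WT_APP23
HEMO	Hemopexin	4.5e-02	2.8e-04	WT_APP23
PGCB	Brevican core protein		1.0e-05	APP23
GRID2	Glutamate receptor ionotropic, delta-2		1.0e-05	APP23
CA2D2	Voltage-dependent calcium channel subunit alpha-2/delta-2		1.8e-04	APP23
SCG2	Secretogranin-2		1.6e-03	APP23
AT2B1	Plasma membrane calcium-transporting ATPase 1		3.2e-03	APP23
SEM3C	Semaphorin-3C		4.6e-03	APP23
NRX2A	Neurexin-2		6.0e-03	APP23
GPM6A	Neuronal membrane glycoprotein M6-a		1.5e-02	APP23
MYPR	Myelin proteolipid protein		1.6e-02	APP23
PLXB2	Plexin-B2		2.4e-02	APP23
GRM3	Metabotropic glutamate receptor 3		5.5e-02	APP23
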