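histotype	accession	gene	protein	mw_kda	pi
SM	A0A494C1T9	FAM83H	Protein FAM83H	149	6.71
SM	P01824	IGHV4-39	Immunoglobulin heavy variable 4-39	13.9	9.26
SM	A0A0A0MRZ8	IGKV3D-11	Immunoglobulin kappa variable 3D-11	12.6	5.29
SM	Q8WY54	PPM1E	Protein phosphatase 1E	83.9	5.01
CS	O14791	APOL1	Apolipoprotein L1	43.9	5.81
CS	A0A0J9YWD6	DEAF1	Deformed epidermal autoregulatory factor 1 homolog (Frag.)	17.7	7.11
CS	E7ETE2	HARS1	Histidyl-tRNA synthetase 1	57.8	5.88
CS	Q9UGL1	KDM5B	Lysine-specific demethylase 5B	175.5	6.7
CS	Q8NG48	LINS1	Protein Lines homolog 1	85.8	6.52
CS	Q9Y2U5	MAP3K2	Mitogen-activated protein kinase kinase kinase 2	69.7	8
CS	P35580	MYH10	Myosin-10	228.9	5.54
CS	Q5VT52	RPRD2	Regulation of nuclear pre-mRNA domain-containing protein 2	155.9	7.42
CG	P62736	ACTA2	Actin, aortic smooth muscle	42	5.39
CG	A0A5F9ZHS1	ANK2	Ankyrin-2	436.8	5.16
CG	P07360	C8G	Complement component C8 gamma chain	22.3	8.31
CG	O94985	CLSTN1	Calsyntenin-1	109.7	4.91
CG	P04406	GAPDH	Glyceraldehyde-3-phosphate dehydrogenase	36	8.46
CG	Q96D09	GPRASP2	G-protein coupled receptor-associated sorting protein 2	93.7	5.01
CG	U3KQK0	H2BC15	Histone H2B	18.8	10.54
CG	P42695	NCAPD3	Condensin-2 complex subunit D3	168.8	7.5
CG	Q86XR2	NIBAN3	Protein Niban 3	77.4	8.63
CG	P32119	PRDX2	Peroxiredoxin-2	21.9	5.97
CG	P29622	SERPINA4	Kallistatin	48.5	7.75
CG	P05543	SERPINA7	Thyroxine-binding globulin	46.3	6.3
CG	Q14515	SPARCL1	SPARC-like protein 1	75.2	4.81
CG	Q9UGK3	STAP2	Signal-transducing adaptor protein 2	44.9	8.16
CG	P24821	TNC	Tenascin	240.7	4.89
CG	Q92752	TNR	Tenascin-R	149.5	4.82
CG	Q96AY4	TTC28	Tetratricopeptide repeat protein 28	270.7	6.89
CG	P13611	VCAN	Versican core protein	372.6	4.51
CG	Q8N720	ZNF655	Zinc-finger protein 655	57.4	7.14
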