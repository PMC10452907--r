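Cell_Adhesion	synthetic membership for testing	TNC	TNR	VCAN	CLSTN1	ANK2	SPARCL1
Genetic_Information_Processing	synthetic membership for testing	HARS1	KDM5B	RPRD2	DEAF1	H2BC15	NCAPD3
Angiogenesis	synthetic membership for testing	KNG1	LRG1	SERPINA4	SPARCL1
Response_to_Bacterium	synthetic membership for testing	ORM1	ORM2	HP	C8G
Apoptosis	synthetic membership for testing	PRDX2	H2BC15
Metabolism	synthetic membership for testing	GAPDH	ALDH1A1	RBP4	APOL1
Kinases	synthetic membership for testing	MAP3K2	PPM1E	STAP2	FAM83H
Acute_Inflammatory_Response	synthetic membership for testing	AHSG	ORM1	ORM2	A2M	HP
Structural_Cytoskeleton	synthetic membership for testing	ACTA2	MYH10	FAM83H	GSN
Peptidase_Inhibitors	synthetic membership for testing	A2M	SERPINA4	SERPINA7	AHSG
Complement_Activation	synthetic membership for testing	C8G	CLU	HP
Lipid_Transport	synthetic membership for testing	APOL1	APOD	APOE	CLU	RBP4
Coagulation	synthetic membership for testing	KNG1	A2M	GSN
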