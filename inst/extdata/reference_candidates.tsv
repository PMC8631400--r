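tissue	accession	parent_name	candidates
adipose	GO:0070162	adiponectin secretion	IL1B
adipose	GO:0060612	adipose tissue development	NAMPT,SORL1,LEP,FTO,PIK3CA,GHRL
adipose	GO:0005901	caveola	ADCY8,SELE,INSR,IRS1,TFPI,HMOX1,FASLG,NOS3
adipose	GO:1904606	fat cell apoptotic process	LEP
adipose	GO:0045444	fat cell differentiation	LEP,FTO,FRZB,ADIPOQ,SORT1,SREBF1,LPL,RARRES2,FABP4,TGFB1,TNF,METRNL,GPX1,FABP3,RETN,FNDC5,IL6,PPARG
adipose	GO:0070341	fat cell proliferation	FTO
adipose	GO:0044321	response to leptin	LEP,LEPR,FGF23,EDN1
adipose	HPA	additional from atlas	ACP5,CD36,CHIT1,GPNMB,ITLN1,MMP9,PLA2G7,PRG4,PTX3,SAA1
liver	GO:0034382	chylomicron remnant clearance	LDLR,LIPC,APOB,APOC3,APOC2,APOC1,APOE
liver	GO:0002384	hepatic immune response	IL6R,IL6
liver	GO:0035733	hepatic stellate cell activation	LEP,GCLC
liver	GO:0061868	hepatic stellate cell migration	
liver	GO:1990922	hepatic stellate cell proliferation	
liver	GO:0097284	hepatocyte apoptotic process	GSN,KRT18
liver	GO:0001889	liver development	FGL1,HAMP,CPB2,EGFR,PIK3CA,REG1A,HMOX1,VTN,IL10,PCSK9,FGF1
liver	GO:0034379	very-low-density lipoprotein particle assembly	APOB,APOC3,APOC1
liver	HPA	additional from atlas	A1BG,A2M,ADAMTS13,AGT,AHSG,AMBP,APOA1,AZGP1,CAT,CD14,CHI3L1,CLU,AGTR1,CPN2,F7,FST,GDF2,HP,HRG,ICAM1,IGFBP2,IL18BP,IL27,KLKB1,KNG1,LBP,LEPR,LRG1,MASP1,MBL2,ORM1,PLA2G2A,PLG,PRDX4,PRG4,PROC,PROS1,RARRES2,RBP4,SAA1,SDC1,SERPINA1,SERPINA3,SERPINC1,SOD1,TF,SERPING1,TNFSF14,TTR
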