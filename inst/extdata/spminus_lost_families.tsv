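copy_class	cog	locus	gene	product	paralogs	localization
several_copies	C	FRAAL2393	hupL1	Uptake hydrogenase large subunit	FRAAL1829	
several_copies	C	FRAAL2391	hupD1	Hydrogenase maturation protein	FRAAL1828	
several_copies	C	FRAAL2392	hupS1	Uptake hydrogenase small subunit precursor	FRAAL1830	SP
several_copies	C	FRAAL3522		Putative Formyl-CoA transferase	FRAAL4675	
several_copies	C	FRAAL3876		Putative acyl-CoA transferases/carnitine dehydratase	FRAAL4764	
several_copies	C	FRAAL2565		Putative polyketide oxygenase/hydroxylase	FRAAL4792,FRAAL2325,FRAAL3051,FRAAL3395	
several_copies	C	FRAAL3041		Putative Dihydrolipoamide acyltransferases	FRAAL5152	
several_copies	E	FRAAL6516		Putative membrane protein	FRAAL1256	TM
several_copies	I	FRAAL2505	atoD	Acetoacetyl-CoA transferase	FRAAL2504,FRAAL3148,FRAAL3149	
several_copies	I	FRAAL4765		Putative enoyl-CoA hydratase	FRAAL2509,FRAAL2514,FRAAL3092,FRAAL3517,FRAAL3973,FRAAL5910,FRAAL6774	
several_copies	I	FRAAL1660		Putative Acyl-CoA dehydrogenase	FRAAL6459	
several_copies	J	FRAAL4260		Putative glutamyl-tRNA(Gln) amidotransferase, subunit A	FRAAL0363,FRAAL3665,FRAAL6013,FRAAL6173	
several_copies	K	FRAAL2359		Putative tetR family transcriptional regulator	FRAAL4751	
several_copies	K	FRAAL1892		Putative HTH-type transcriptional regulator	FRAAL4821	
several_copies	K	FRAAL6046		Transcriptional regulator (MerR-family)	FRAAL6751	
several_copies	K	FRAAL1282		Putative merR family transcriptional regulator	FRAAL6823	
several_copies	L	FRAAL5342		Hypothetical protein; putative DNA helicase II homolog	FRAAL0267	
several_copies	L	FRAAL6137		Putative ribosylglycoyhydrolase	FRAAL0303,FRAAL5802,FRAAL6736	
several_copies	P	FRAAL1452		Putative ABC transporter, permease protein	FRAAL1453,FRAAL1557	TM
several_copies	Q	FRAAL3901		Putative Phytoene dehydrogenase	FRAAL2168	
several_copies	R	FRAAL0277	surE	Acid phosphatase SurE, survival protein	FRAAL6200	SP
several_copies	T	FRAAL3898		Hypothetical protein	FRAAL6520	
several_copies	NI	FRAAL6489		Hypothetical protein	FRAAL1398	TM
several_copies	NI	FRAAL1769		Hypothetical protein	FRAAL5611	
single_copy	C	FRAAL1457		Putative Xanthine dehydrogenase		
single_copy	C	FRAAL4787		Putative N-glycosyltransferase		
single_copy	C	FRAAL3448	glpQ	Glycerophosphoryl diester phosphodiesterase		SP
single_copy	D	FRAAL2959		ATP/GTP binding protein		TM
single_copy	E	FRAAL5354		Hypothetical protein		
single_copy	E	FRAAL4450		Putative Monomeric sarcosine oxidase (MSOX)		
single_copy	E	FRAAL1891		Putative sarcosine oxidase subunit beta		
single_copy	E	FRAAL4839		ABC peptide transporter		SP
single_copy	F	FRAAL3674		Uridine kinase		
single_copy	G	FRAAL0592		Putative ROK family transcriptional regulator		
single_copy	H	FRAAL6157		Conserved hypothetical protein; putative Pantothenate kinase		
single_copy	I	FRAAL2810		Hypothetical protein		
single_copy	K	FRAAL0335		Putative LuxR family transcriptional regulator		
single_copy	K	FRAAL1455		Hypothetical protein		
single_copy	K	FRAAL1658		Putative two-component system response regulator		
single_copy	K	FRAAL2338		Hypothetical protein		
single_copy	K	FRAAL2354		Putative DNA-binding protein		
single_copy	K	FRAAL3054		Hypothetical protein		
single_copy	K	FRAAL3611		Putative MarR family transcriptional regulator		
single_copy	K	FRAAL3970		Putative repressor		
single_copy	K	FRAAL3977		Putative TetR-family transcriptional regulator		
single_copy	K	FRAAL4738		Putative LuxR-family transcriptional regulator		
single_copy	L	FRAAL0558		Conserved hypothetical protein; putative DNA-glycosylase domain		
single_copy	L	FRAAL4221		Hypothetical protein		
single_copy	O	FRAAL1895		Putative heat shock protein 16		
single_copy	O	FRAAL2394		Thioredoxin-like protein		
single_copy	O	FRAAL5033		Putative alkaline serine protease		SP
single_copy	P	FRAAL3036		Hypothetical protein		
single_copy	P	FRAAL3387		Cyclohexanone monooxygenase		SP
single_copy	P	FRAAL3502		Hypothetical protein; putative Rieske [2Fe-2S] domain		
single_copy	R	FRAAL0327		Putative amidohydrolase		
single_copy	R	FRAAL5340		Hypothetical protein		
single_copy	R	FRAAL3906		Putative integral membrane transport protein		TM
single_copy	R	FRAAL3907		Putative ABC-type uncharacterized transport system		TM
single_copy	S	FRAAL1385		Hypothetical protein		
single_copy	S	FRAAL3029		Hypothetical protein		
single_copy	S	FRAAL1789		Hypothetical protein		TM
single_copy	T	FRAAL1745		Tellurium resistance protein terE		
single_copy	U	FRAAL4430		Putative signal peptide		SP
single_copy	NI	FRAAL0290		Hypothetical protein		
single_copy	NI	FRAAL1186		Hypothetical protein		
single_copy	NI	FRAAL6274		Hypothetical protein		
single_copy	NI	FRAAL6706		Hypothetical protein		
single_copy	NI	FRAAL3025	gvpA	Gas vesicle synthesis-like protein		
single_copy	NI	FRAAL3026	gvpF	Gas vesicle protein F		
single_copy	NI	FRAAL1685		Putative IMP dehydrogenase/GMP reductase domain		
single_copy	NI	FRAAL1686		Putative P-loop containing nucleotide triphosphate hydrolase domain		
single_copy	NI	FRAAL2305		Hypothetical protein		
single_copy	NI	FRAAL2306		Hypothetical protein		
single_copy	NI	FRAAL2795		Hypothetical protein		
single_copy	NI	FRAAL3310		Hypothetical protein		
single_copy	NI	FRAAL3311		Hypothetical protein		
single_copy	NI	FRAAL3894		Hypothetical protein		
single_copy	NI	FRAAL4437		Hypothetical protein		
single_copy	NI	FRAAL4895		Hypothetical protein		
single_copy	NI	FRAAL4893		Putative N-acetylmuramoyl-L-alanine amidase domains		SP
single_copy	NI	FRAAL0360		Putative signal peptide		SP
single_copy	NI	FRAAL5030		Putative signal peptide		SP
single_copy	NI	FRAAL5032		Putative signal peptide		SP
single_copy	NI	FRAAL4294		Putative signal peptide		SP
single_copy	NI	FRAAL4721		Putative signal peptide		SP
single_copy	NI	FRAAL5515		Putative lipoprotein		SP
single_copy	NI	FRAAL6270		Putative signal peptide		TM
single_copy	NI	FRAAL3669		Hypothetical protein		TM
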