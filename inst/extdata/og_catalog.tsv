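# Default FFA-production OG catalog: 49 orthologous groups (13 nOG, 24 pOG,
# 12 rOG), 64 member proteins. OG ids are KEGG Orthology (K*) or eggNOG
# (cyaNOG*/virNOG*) identifiers; action labels record the engineering evidence
# class behind each criterion. The second member listed for some OGs is an
# alias/paralog token reconstructed from alternate gene names (the full curated
# membership is organism-specific); domain_accessions are intentionally empty
# and should be filled in with the Pfam families required for each member.
og_id	category	action_label	member_protein_id	domain_accessions
K00873	rOG	present	pykf	
K00873	rOG	present	pyk	
K01007	rOG	present	pps	
K00161	rOG	present	pdhA	
K00162	rOG	present	pdhB	
K00627	rOG	present	odhB	
K00627	rOG	present	pdhC	
K00382	rOG	present	phdD	
K00382	rOG	present	ipdA	
K00648	rOG	present	fabH	
K00645	rOG	present	fabD	
K09458	rOG	present	fabF	
K02372	rOG	present	fabZ	
K00208	rOG	present	fabI	
K01046	rOG	present	lipase	
K01046	rOG	present	E3.1.1.3	
K01962	pOG	overexpression	accA	
K01963	pOG	overexpression	accD	
K01961	pOG	overexpression	accC	
K02160	pOG	overexpression	accB	
K00432	pOG	overexpression	Synpcc7942_1214	
K00432	pOG	overexpression	gpx	
K04564	pOG	overexpression	Synpcc7942_0801	
K04564	pOG	overexpression	SOD2	
K06198	pOG	overexpression	Synpcc7942_0437	
K06198	pOG	overexpression	coiA	
K03782	pOG	overexpression	Synpcc7942_1656	
K03782	pOG	overexpression	katG	
K03621	pOG	overexpression	plsX	
K08591	pOG	overexpression	plsY	
K00655	pOG	overexpression	plsC	
virNOG10454	pOG	overexpression	PDAT1	
virNOG19439	pOG	overexpression	oleosins	
K14457	pOG	insert	DGTT2	
K14457	pOG	insert	MGAT2	
virNOG24576	pOG	overexpression	LCIA	
virNOG22763	pOG	overexpression	LCIB	
K00006	pOG	overexpression	GPDH	
K01601	pOG	insert	rbcL	
K01602	pOG	insert	rbcS	
K01648	pOG	insert	acl	
K01648	pOG	insert	ACLY	
K10804	pOG	insert	tesA	
K10804	pOG	insert	tesA_Ec	
K10781	pOG	insert	fatB	
K10782	pOG	insert	fat1	
K10782	pOG	insert	FATA	
K14075	pOG	insert	gpl	
K14075	pOG	insert	PLRP2	
K01595	nOG	underexpression	ppc	
K01897	nOG	knockout	fadD	
K01897	nOG	knockout	aas	
K00059	nOG	knockout	fabG	
K00626	nOG	knockout	thi	
K11003	nOG	knockout	hemolysin	
cyaNOG01264	nOG	knockout	PBP2	
K13788	nOG	knockout	pta	
K13282	nOG	knockout	slr2001	
K03802	nOG	knockout	slr2002	
cyaNOG01069	nOG	knockout	porin	
K13535	nOG	underexpression	Thaps3_264297	
K13535	nOG	underexpression	CLD1	
K00030	nOG	knockout	idh	
K03603	nOG	knockout	fadR	
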