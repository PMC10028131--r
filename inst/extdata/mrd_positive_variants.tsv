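sample_id	gene	chromosome	exon	cdot	pdot	vaf	variant_type
69168	CREBBP	chr16	Exon31+1424	c.6596A>T	p.Q2199L	0.003217	Substitution
69168	EZH2	chr7	Exon10-30	c.1209_1211del	p.E404del	0.00552	Deletion
69168	TP53	chr17	Exon5+1	c.376T>G	p.Y126D	0.003066	Substitution
79060	TP53	chr17	Exon6+48	c.607G>A	p.V203M	0.002152	Substitution
52813	NF1	chr17	Exon47-68	c.6995C>G	p.S2332*	0.005093	Substitution
63144	EZH2	chr7	Exon2-56	c.62C>G	p.S21*	0.003297	Substitution
63144	GLI3	chr7	Exon15+1996	c.4427del	p.N1476Tfs*12	0.003307	Deletion
63144	NF1	chr17	Exon3-13	c.276del	p.K92Nfs*11	0.003922	Deletion
65536	APC	chr5	Exon16-3556	c.7090del	p.M2364Cfs*10	0.003487	Deletion
65536	GLI3	chr7	Exon15+1996	c.4427del	p.N1476Tfs*12	0.003692	Deletion
92916	TERT	chr5		c.-124C>T		0.010394	Substitution
92916	TP53	chr17	Exon7-36	c.747G>T	p.R249S	0.010289	Substitution
92916	TP53	chr17	IVS3-2	c.97-2A>T		0.00618	Substitution
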