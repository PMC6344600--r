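entry_id	family	role	hemes	source_tag
MtrA_syn	MtrA	periplasmic_MHC	10	synthetic; modeled on Shewanella oneidensis MR-1 MtrA (decaheme periplasmic Cyt c)
MtrB_syn	MtrB	porin	0	synthetic; modeled on S. oneidensis MR-1 MtrB (outer-membrane porin)
MtrC_syn	MtrC	extracellular_MHC	10	synthetic; modeled on S. oneidensis MR-1 MtrC (decaheme extracellular Cyt c)
MtoA_syn	MtoA	periplasmic_MHC	10	synthetic; modeled on Sideroxydans lithotrophicus ES-1 MtoA
MtoB_syn	MtoB	porin	0	synthetic; modeled on S. lithotrophicus ES-1 MtoB
PioA_syn	PioA	periplasmic_MHC	10	synthetic; modeled on Rhodopseudomonas palustris TIE-1 PioA
PioB_syn	PioB	porin	0	synthetic; modeled on R. palustris TIE-1 PioB
OmaB_syn	OmaB	periplasmic_MHC	8	synthetic; modeled on Geobacter sulfurreducens OmaB (octaheme periplasmic Cyt c)
OmbB_syn	OmbB	porin	0	synthetic; modeled on G. sulfurreducens OmbB (porin)
OmcB_syn	OmcB	extracellular_MHC	12	synthetic; modeled on G. sulfurreducens OmcB (dodecaheme outer-membrane Cyt c)
OmcE_syn	OmcE	outer_surface_MHC	4	synthetic; modeled on G. sulfurreducens OmcE
OmcS_syn	OmcS	outer_surface_MHC	6	synthetic; modeled on G. sulfurreducens OmcS
OmcZ_syn	OmcZ	outer_surface_MHC	8	synthetic; modeled on G. sulfurreducens OmcZ
Cyc2_syn	Cyc2	cyc2	1	synthetic; modeled on Acidithiobacillus ferrooxidans Cyc2 (monoheme, C-terminal porin fold)
porin_other_syn	porin_other	porin	0	synthetic; generic outer-membrane porin model for organization-based PCC search
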