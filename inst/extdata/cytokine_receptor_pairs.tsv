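ligand	receptor	name
Cxcl1	Cxcr2	Cxcl1-Cxcr2
Cxcl16	Cxcr6	Cxcl16-Cxcr6
g00001	g00002	decoy-1
g00003	g00004	decoy-2
g00005	g00006	decoy-3
g00007	g00008	decoy-4
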