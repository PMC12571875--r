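PDGF_SIGNALING	synthetic PDGF receptor signalling set (ligands, receptors, downstream response)	PDGFA	PDGFB	PDGFC	PDGFD	PDGFRA	PDGFRB	PIK3R1	STAT3	MAPK3	SPRY1	JUN	FOS
TGFB_SIGNALING	synthetic TGF-beta signalling set (ligand, receptors, downstream response)	TGFB1	TGFBR1	TGFBR2	SMAD3	SMAD7	SERPINE1	JUNB	SKIL	ID1	TGIF1
FIBROSIS	synthetic extracellular-matrix / fibrosis set	COL1A1	COL4A1	FN1	LUM	TIMP1
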