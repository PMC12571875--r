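interaction_id,ligand_genes,receptor_genes,pathway,category
PDGFA_PDGFRA,PDGFA,PDGFRA,PDGF,secreted
PDGFA_PDGFRB,PDGFA,PDGFRB,PDGF,secreted
PDGFB_PDGFRB,PDGFB,PDGFRB,PDGF,secreted
PDGFC_PDGFRA,PDGFC,PDGFRA,PDGF,secreted
PDGFD_PDGFRB,PDGFD,PDGFRB,PDGF,secreted
TGFB1_TGFBR,TGFB1,TGFBR1;TGFBR2,TGFb,secreted
VEGFA_FLT1,VEGFA,FLT1,VEGF,secreted
DLL4_NOTCH1,DLL4,NOTCH1,NOTCH,contact
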