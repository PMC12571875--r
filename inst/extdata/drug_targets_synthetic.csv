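drug_id,target_gene,action
nintedanib,PDGFRA,inhibitor
nintedanib,PDGFRB,inhibitor
nintedanib,FLT1,inhibitor
nintedanib,KDR,inhibitor
nintedanib,FGFR1,inhibitor
imatinib,PDGFRA,inhibitor
imatinib,PDGFRB,inhibitor
imatinib,KIT,inhibitor
imatinib,ABL1,inhibitor
fostamatinib,SYK,inhibitor
fostamatinib,TGFBR1,inhibitor
fostamatinib,TGFBR2,inhibitor
fostamatinib,MAPK3,inhibitor
galunisertib,TGFBR1,antagonist
becaplermin,PDGFRB,agonist
becaplermin,PDGFRA,agonist
trametinib,MAP2K1,inhibitor
trametinib,MAP2K2,inhibitor
aspirin,PTGS1,inhibitor
aspirin,PTGS2,inhibitor
lisinopril,ACE,inhibitor
olaparib,PARP1,inhibitor
seribantumab,ERBB3,binder
sunitinib,PDGFRA,inhibitor
sunitinib,PDGFRB,inhibitor
sunitinib,KIT,inhibitor
sunitinib,FLT3,inhibitor
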