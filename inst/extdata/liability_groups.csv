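group,target
CV,ACHE
CV,ADORA2A
CV,ADRA1A
CV,ADRA2A
CV,ADRB2
CV,AVPR1A
CV,CHRM1
CV,DRD1
CV,DRD2
CV,HRH1
CV,HRH2
CV,HTR1B
CV,HTR2A
CV,HTR2B
CV,KCNH2
CV,MAOA
CV,OPRD1
CV,OPRK1
CV,OPRM1
CV,PDE3A
CV,PTGS2
CV,SCN5A
CV,SLC6A2
CV,SLC6A4
CNS,ADORA2A
CNS,ADRA1A
CNS,ADRA2A
CNS,CHRM1
CNS,CNR1
CNS,DRD1
CNS,DRD2
CNS,EDNRA
CNS,HTR1A
CNS,HTR1B
CNS,HTR2A
CNS,MAOA
CNS,OPRD1
CNS,OPRK1
CNS,OPRM1
CNS,PDE4D
CNS,SLC6A2
CNS,SLC6A3
CNS,SLC6A4
GI,ACHE
GI,ADRA1A
GI,ADRB1
GI,CCKAR
GI,CHRM1
GI,CHRM3
GI,HRH2
GI,HTR3A
GI,OPRK1
GI,OPRM1
GI,PPARA
GI,PPARD
GI,PTGS1
ED,AR
ED,DRD2
ED,EDNRA
ED,ESR1
ED,HTR1A
ED,HTR3A
ED,NR3C1
PU,ACHE
PU,ADRB2
PU,CHRM3
PU,HTR2B
PU,PTGS1
RE,AVPR1A
RE,PTGS1
IM,CNR2
IM,HRH1
IM,LCK
IM,NR3C1
IM,PDE4D
IM,PTGS2
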