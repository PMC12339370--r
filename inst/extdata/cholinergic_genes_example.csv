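"gene","tier","functional_class"
"ACHE","core","cholinesterase/synthesis/transport"
"BCHE","core","cholinesterase/synthesis/transport"
"CHAT","core","cholinesterase/synthesis/transport"
"SLC5A7","core","cholinesterase/synthesis/transport"
"SLC18A3","core","cholinesterase/synthesis/transport"
"CHRNA4","core","receptor"
"CHRNA7","core","receptor"
"CHRNB2","core","receptor"
"CHRM1","core","receptor"
"CHRM2","core","receptor"
"CHRM3","core","receptor"
"CHRM4","core","receptor"
"CHRM5","core","receptor"
"CHRNA3","core","receptor"
"CHRNB4","core","receptor"
"IL6","peripheral","auxiliary/inflammatory/metabolic"
"CHKB","peripheral","auxiliary/inflammatory/metabolic"
"CHKA","peripheral","auxiliary/inflammatory/metabolic"
"IL1B","peripheral","auxiliary/inflammatory/metabolic"
"IL10","peripheral","auxiliary/inflammatory/metabolic"
"TNF","peripheral","auxiliary/inflammatory/metabolic"
"NFKB1","peripheral","auxiliary/inflammatory/metabolic"
"BDNF","peripheral","auxiliary/inflammatory/metabolic"
"NGF","peripheral","auxiliary/inflammatory/metabolic"
"NTRK1","peripheral","auxiliary/inflammatory/metabolic"
"NTRK2","peripheral","auxiliary/inflammatory/metabolic"
"RIC3","peripheral","auxiliary/inflammatory/metabolic"
"LYNX1","peripheral","auxiliary/inflammatory/metabolic"
"CLOCK","peripheral","auxiliary/inflammatory/metabolic"
"ARNTL","peripheral","auxiliary/inflammatory/metabolic"
"PER1","peripheral","auxiliary/inflammatory/metabolic"
"PER2","peripheral","auxiliary/inflammatory/metabolic"
"CRY1","peripheral","auxiliary/inflammatory/metabolic"
"CRY2","peripheral","auxiliary/inflammatory/metabolic"
"CRH","peripheral","auxiliary/inflammatory/metabolic"
"CRHR1","peripheral","auxiliary/inflammatory/metabolic"
"NR3C1","peripheral","auxiliary/inflammatory/metabolic"
"FKBP5","peripheral","auxiliary/inflammatory/metabolic"
"PCYT1A","peripheral","auxiliary/inflammatory/metabolic"
"PCYT1B","peripheral","auxiliary/inflammatory/metabolic"
"PLD1","peripheral","auxiliary/inflammatory/metabolic"
"PLD2","peripheral","auxiliary/inflammatory/metabolic"
"PEMT","peripheral","auxiliary/inflammatory/metabolic"
"CHPT1","peripheral","auxiliary/inflammatory/metabolic"
"CEPT1","peripheral","auxiliary/inflammatory/metabolic"
"ETNK1","peripheral","auxiliary/inflammatory/metabolic"
"PNLIP","peripheral","auxiliary/inflammatory/metabolic"
"LYPLA1","peripheral","auxiliary/inflammatory/metabolic"
"LYPLA2","peripheral","auxiliary/inflammatory/metabolic"
"APOE","peripheral","auxiliary/inflammatory/metabolic"
"MAPK1","peripheral","auxiliary/inflammatory/metabolic"
"MAPK3","peripheral","auxiliary/inflammatory/metabolic"
"AKT1","peripheral","auxiliary/inflammatory/metabolic"
"PIK3CA","peripheral","auxiliary/inflammatory/metabolic"
"PRKCA","peripheral","auxiliary/inflammatory/metabolic"
"PRKCB","peripheral","auxiliary/inflammatory/metabolic"
"CAMK2A","peripheral","auxiliary/inflammatory/metabolic"
"CAMK2B","peripheral","auxiliary/inflammatory/metabolic"
"FOS","peripheral","auxiliary/inflammatory/metabolic"
"JUN","peripheral","auxiliary/inflammatory/metabolic"
"EGR1","peripheral","auxiliary/inflammatory/metabolic"
"CREB1","peripheral","auxiliary/inflammatory/metabolic"
"STAT3","peripheral","auxiliary/inflammatory/metabolic"
"IL4","peripheral","auxiliary/inflammatory/metabolic"
"IL13","peripheral","auxiliary/inflammatory/metabolic"
"IFNG","peripheral","auxiliary/inflammatory/metabolic"
"TGFB1","peripheral","auxiliary/inflammatory/metabolic"
"TLR4","peripheral","auxiliary/inflammatory/metabolic"
"CD36","peripheral","auxiliary/inflammatory/metabolic"
"P2RX7","peripheral","auxiliary/inflammatory/metabolic"
"GFAP","peripheral","auxiliary/inflammatory/metabolic"
"S100B","peripheral","auxiliary/inflammatory/metabolic"
"SNCA","peripheral","auxiliary/inflammatory/metabolic"
"APP","peripheral","auxiliary/inflammatory/metabolic"
"BACE1","peripheral","auxiliary/inflammatory/metabolic"
"MAPT","peripheral","auxiliary/inflammatory/metabolic"
"SORT1","peripheral","auxiliary/inflammatory/metabolic"
"SELP","peripheral","auxiliary/inflammatory/metabolic"
"VCAM1","peripheral","auxiliary/inflammatory/metabolic"
"ICAM1","peripheral","auxiliary/inflammatory/metabolic"
"NOS1","peripheral","auxiliary/inflammatory/metabolic"
"NOS2","peripheral","auxiliary/inflammatory/metabolic"
"NOS3","peripheral","auxiliary/inflammatory/metabolic"
"EDN1","peripheral","auxiliary/inflammatory/metabolic"
"AGT","peripheral","auxiliary/inflammatory/metabolic"
"ACE","peripheral","auxiliary/inflammatory/metabolic"
"ADRB2","peripheral","auxiliary/inflammatory/metabolic"
"ADRA2A","peripheral","auxiliary/inflammatory/metabolic"
"NPY","peripheral","auxiliary/inflammatory/metabolic"
"TAC1","peripheral","auxiliary/inflammatory/metabolic"
"GAL","peripheral","auxiliary/inflammatory/metabolic"
"VIP","peripheral","auxiliary/inflammatory/metabolic"
"SST","peripheral","auxiliary/inflammatory/metabolic"
"OPRM1","peripheral","auxiliary/inflammatory/metabolic"
"POMC","peripheral","auxiliary/inflammatory/metabolic"
"HCRT","peripheral","auxiliary/inflammatory/metabolic"
"TRH","peripheral","auxiliary/inflammatory/metabolic"
"GNB3","peripheral","auxiliary/inflammatory/metabolic"
"GNAQ","peripheral","auxiliary/inflammatory/metabolic"
"RGS2","peripheral","auxiliary/inflammatory/metabolic"
"RGS4","peripheral","auxiliary/inflammatory/metabolic"
"ARRB1","peripheral","auxiliary/inflammatory/metabolic"
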