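"chain_class","position","scheme","provenance"
"heavy","2","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
"heavy","27","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
"heavy","28","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
"heavy","29","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
"heavy","30","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
"heavy","47","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
"heavy","48","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
"heavy","49","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
"heavy","67","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
"heavy","69","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
"heavy","71","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
"heavy","73","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
"heavy","78","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
"heavy","93","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
"heavy","94","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
"heavy","103","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
"kappa","2","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
"kappa","4","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
"kappa","35","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
"kappa","36","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
"kappa","46","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
"kappa","47","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
"kappa","48","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
"kappa","49","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
"kappa","64","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
"kappa","66","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
"kappa","68","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
"kappa","69","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
"kappa","71","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
"kappa","98","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
"lambda","2","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
"lambda","4","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
"lambda","35","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
"lambda","36","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
"lambda","46","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
"lambda","47","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
"lambda","48","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
"lambda","49","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
"lambda","64","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
"lambda","66","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
"lambda","68","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
"lambda","69","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
"lambda","71","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
"lambda","98","kabat","Foote & Winter (1992) J Mol Biol 224:487-499 framework positions underlying CDR loops"
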