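subtype	site
ESCC	C15
GACA	C16
COCA	C18
LIHC	C22
PAAD	C25
LUAD	C34
LUSC	C34
SKCM	C43
BRCA	C50
CESC	C53
UCEC	C54
OVCA	C56
PRCA	C61
KIRC	C64
BLCA	C67
GBM	C71
PTC	C73
HNSC	C10
LYMP	C85
LEUK	C91
NPCA	C11
BDCA	C24
STSA	C49
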