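alias	official
P53	TP53
ERBB1	EGFR
HER1	EGFR
MLL2	KMT2D
MLL3	KMT2C
C-K-RAS	KRAS
KRAS2	KRAS
B-RAF1	BRAF
MMAC1	PTEN
DEC	APC
CDKN2	CDKN2A
P16	CDKN2A
HER2	ERBB2
NEU	ERBB2
FLJ21439	LRP1B
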