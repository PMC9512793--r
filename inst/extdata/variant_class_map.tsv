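token	class
Missense_Mutation	missense
Nonsense_Mutation	nonsense
Frame_Shift_Del	frameshift
Frame_Shift_Ins	frameshift
In_Frame_Del	inframe_indel
In_Frame_Ins	inframe_indel
Splice_Site	splice
Splice_Region	splice
Silent	silent
3'UTR	noncoding
5'UTR	noncoding
3'Flank	noncoding
5'Flank	noncoding
Intron	noncoding
IGR	noncoding
RNA	noncoding
lincRNA	noncoding
Translation_Start_Site	other
Nonstop_Mutation	other
SV	SV
Fusion	fusion
Fusion_Gene	fusion
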