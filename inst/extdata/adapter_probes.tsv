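label	sequence	platform
Illumina TruSeq adapter	AGATCGGAAGAG	illumina
Illumina TruSeq adapter (RC)	CTCTTCCGATCT	illumina
Illumina Nextera transposase	CTGTCTCTTATA	illumina
Illumina Nextera transposase (RC)	TATAAGAGACAG	illumina
ONT ligation kit adapter	ACTTCGTTCAGT	ont
ONT ligation kit adapter (RC)	ACTGAACGAAGT	ont
ONT rapid adapter	GTTTTCGCATTT	ont
ONT rapid adapter (RC)	AAATGCGAAAAC	ont
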