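mirna	gene	source
mir-155	FOS	synthetic
mir-155	RIPK1	synthetic
mir-155	TAB2	synthetic
mir-155	JUN	synthetic
mir-155	IL13RA1	synthetic
mir-146a	IRAK1	synthetic
mir-146a	TRAF6	synthetic
mir-146a	IL6	synthetic
mir-9	NFKB1	synthetic
mir-9	TGFB1	synthetic
mir-9	MYC	synthetic
mir-147b	IRAK1	synthetic
mir-147b	TRAF6	synthetic
mir-147b	IRAK2	synthetic
mir-193a	MAFB	synthetic
mir-193a	PTGS2	synthetic
mir-193a	ERBB2	synthetic
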