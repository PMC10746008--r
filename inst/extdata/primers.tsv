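name	specificity	seq	role
27F	EUB	AGAGTTTGATCCTGGCTCAG	forward
1492R	UNIV	GGTTACCTTGTTACGACTT	reverse
GS.619F	GSB	GGGGTTAAATCCATGTGTGCT	forward
GS.1144R	GSB	CAGTTCARTTAGAGTCC	reverse
GSB600F	GSB	GGGGGTTAAATCCATGTG	forward
1392R	UNIV	ACGGGCGGTGTGTAC	reverse
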