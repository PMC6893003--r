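type	size	clusters	source
identity	20	A-C-D-E-F-G-H-I-K-L-M-N-P-Q-R-S-T-V-W-Y	identity alphabet, no reduction
hp	2	ACFGILMPVWY-DEHKNQRST	binary hydrophobic/polar partition
murphy	2	LVIMCAGSTPFYW-EDNQKRH	Murphy, Wallqvist & Levy (2000) BLOSUM50-based reduction
murphy	4	LVIMC-AGSTP-FYW-EDNQKRH	Murphy, Wallqvist & Levy (2000) BLOSUM50-based reduction
murphy	8	LVIMC-AG-ST-P-FYW-EDNQ-KR-H	Murphy, Wallqvist & Levy (2000) BLOSUM50-based reduction
murphy	10	LVIM-C-A-G-ST-P-FYW-EDNQ-KR-H	Murphy, Wallqvist & Levy (2000) BLOSUM50-based reduction
murphy	15	LVIM-C-A-G-S-T-P-FY-W-E-D-N-Q-KR-H	Murphy, Wallqvist & Levy (2000) BLOSUM50-based reduction
hydropathy	3	CMFILVW-AGHPSTY-RKEDQN	three-state hydropathy classes
charge	3	KRH-DE-ACFGILMNPQSTVWY	charge classes: basic, acidic, neutral
wang	5	CMFILVWY-ATH-GP-DE-SNQRK	Wang & Wang (1999) five-letter folding alphabet
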