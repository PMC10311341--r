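# Published instance counts of the curated internal-loop motif dataset
# (well-known structural motif families).
family	abbrev	n_instances
Kink-turn	KT	67
reverse-Kink-turn	rKT	8
Sarcin-ricin	SR	74
C-loop	CL	44
E-loop	EL	49
Hook-turn	HT	34
Tandem-shear	TS	45
Tetraloop-receptor	TR	19
L1-complex	L1C	6
Rope-sling	RS	12
T-loop	TL	2
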