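# Published participating-instance counts for similar family pairs of the
# curated internal-loop dataset: number of instances of each family that
# take part in the selected best-aligned inter-family pairs.
family_a	family_b	mode	participants_a	participants_b
EL	TS	interaction	13	25
EL	TS	coordinate	31	10
EL	HT	coordinate	42	25
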