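FusionGene	Rank	Score
DTX3L-MYST3	91	12.1
MYST3-SLK	193	6.3
CREBBP-TTC28	401	2.9
MYST3-DNAJC14	606	1.4
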