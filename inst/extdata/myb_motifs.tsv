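motif_id	consensus
MYBCORE	CNGTTR
MBS	CAACTG
MYBPLANT	MACCWAMC
MYB1AT	WAACCA
MRE	AACCTAA
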