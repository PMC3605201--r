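source	n_rels
NCI	58
MSH	45
OMIM	44
MTH	38
LNC	20
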