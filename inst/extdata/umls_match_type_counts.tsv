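corpus	exact	left_substring	between_2
pubmed	789	591	632
clinicaltrials	409	225	155
internal	24	25	38
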