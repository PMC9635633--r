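repeat_class	repeat_family	count	total_bp
LTR	ERV1	349	167577
LINE	CR1-F	246	88097
DNA_transposon	hAT-Charlie	2	721
tandem	TRF	29	7333
simple	(TA)n	103	5301
low_complexity	A-rich	28	1752
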