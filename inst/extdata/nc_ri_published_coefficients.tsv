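scheme	role	cat	level	cont	estimate
RGE	intercept	NA	NA	NA	0.267
RGE	main	NA	NA	RI	-0.013
RGE	level	race	NHW	NA	0
RGE	level	race	NHB	NA	-0.670
RGE	level	race	Hisp	NA	-0.191
RGE	interaction	race	NHW	RI	0
RGE	interaction	race	NHB	RI	-0.057
RGE	interaction	race	Hisp	RI	0.034
ABC	intercept	NA	NA	NA	0.014
ABC	main	NA	NA	RI	-0.032
ABC	level	race	NHW	NA	0.253
ABC	level	race	NHB	NA	-0.417
ABC	level	race	Hisp	NA	0.062
ABC	interaction	race	NHW	RI	0.018
ABC	interaction	race	NHB	RI	-0.038
ABC	interaction	race	Hisp	RI	0.052
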