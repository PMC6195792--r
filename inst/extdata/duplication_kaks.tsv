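# Published Ka and Ks estimates for the maize CNGC segmental duplication
# pair and maize-Sorghum/rice/Brachypodium orthologous pairs, used as inputs
# to the ratio/divergence-date arithmetic (synonymous clock rate
# lambda = 6.5e-9 substitutions/site/year).
gene_a	gene_b	ka	ks
ZmCNGC11	ZmCNGC10	0.0258	0.1829
ZmCNGC5	Sobic.001G155100	0.5298	0.8917
ZmCNGC12	Sobic.009G188800	0.095	0.4878
ZmCNGC12	Sobic.003G317700	0.0306	0.0993
ZmCNGC5	LOC_Os03g44440	0.7415	1.2253
ZmCNGC12	LOC_Os05g42250	0.1187	0.4278
ZmCNGC12	LOC_Os01g57370	0.073	0.3017
ZmCNGC5	Bradi1g13740	0.7912	1.1721
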