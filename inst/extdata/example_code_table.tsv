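# SYNTHETIC example recognition-code table -- NOT the published table.
# Log-likelihood ratios per (aa5, aa_last) amino-acid combination and RNA
# base, for documentation and examples only. Real analyses must supply a
# table derived from observed motif/base association frequencies.
aa5	aa_last	A	C	G	U
T	D	1.6	-1.2	0.2	-1.1
T	N	1.3	-0.9	-1.0	0.4
S	D	0.3	-0.8	1.4	-1.2
S	N	-0.7	0.2	-1.1	1.5
N	D	-0.9	0.1	-0.6	1.2
N	S	-0.5	1.3	-1.0	0.1
N	N	-0.2	0.9	-0.8	0.6
P	D	0.8	-0.4	0.5	-0.9
G	D	0.2	0.3	-0.5	0.1
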