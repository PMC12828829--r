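element	shift	mass	abundance
C	0	12.0000000	0.9893
C	1	13.0033548	0.0107
H	0	1.0078250319	0.999885
H	1	2.0141017779	0.000115
D	0	2.0141017779	1.0
N	0	14.0030740048	0.99636
N	1	15.0001088982	0.00364
O	0	15.9949146196	0.99757
O	1	16.9991317012	0.00038
O	2	17.9991610043	0.00205
P	0	30.9737616320	1.0
S	0	31.9720710015	0.9499
S	1	32.9714587600	0.0075
S	2	33.9678669000	0.0425
S	4	35.9670807600	0.0001
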