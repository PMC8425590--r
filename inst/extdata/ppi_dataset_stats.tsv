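dataset	n_nodes	n_edges	avg_degree	clustering
Yeast-Tong	964	3846	7.98	0.15
Yeast-Krogan	2708	7123	5.26	0.19
Human	6657	32307	9.52	0.07
E.coli	312	5108	32.74	0.19
Mouse	786	1975	5.03	0.15
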