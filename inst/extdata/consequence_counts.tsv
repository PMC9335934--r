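consequence	fn27	common	rare
splice_donor	0	1786	939
splice_acceptor	5	1838	922
stop_gained	0	4539	2797
frameshift	34	11359	6364
stop_lost	0	819	235
start_lost	0	810	317
inframe_insertion	0	4959	1665
inframe_deletion	0	4603	2490
protein_altering	0	242	127
missense	68	204987	87537
splice_region	13	38143	14205
start_retained	0	112	28
synonymous	29	167608	58830
stop_retained	0	436	148
coding_sequence	0	486	256
5' UTR	19	140683	48300
3' UTR	28	213299	73596
intron	263	1789836	639990
upstream	905	5325487	1721428
downstream	820	4764026	1572140
intergenic	886	3364380	1458227
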