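phase	label	start_year	end_year	publications	authors	mean_authors	journals
Phase 1	1951-1960	1951	1960	507	794	1.83	218
Phase 2	1961-1990	1961	1990	17444	31787	2.90	2153
Phase 3	1991-2000	1991	2000	11517	28818	3.91	1798
Phase 4	2001-2018	2001	2018	33919	118857	5.33	3865
Total	1951-2018	1951	2018	63387	171559	4.39	5443
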