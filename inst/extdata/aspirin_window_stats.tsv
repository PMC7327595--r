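label	start_year	end_year	publications	authors	mean_authors	journals
1951-1955	1951	1955	208	318	1.76	117
1956-1960	1956	1960	299	498	1.88	159
1961-1965	1961	1965	748	1310	2.01	301
1966-1970	1966	1970	1268	2167	2.12	418
1971-1975	1971	1975	2766	4880	2.40	696
1976-1980	1976	1980	3797	7419	2.71	895
1981-1985	1981	1985	4395	10011	3.16	1033
1986-1990	1986	1990	4470	11600	3.50	1101
1991-1995	1991	1995	5164	14044	3.69	1256
1996-2000	1996	2000	6353	17694	4.10	1314
2001-2005	2001	2005	8099	27784	4.22	1719
2006-2010	2006	2010	9366	35313	4.94	1974
2011-2015	2011	2015	10436	44603	5.78	2410
2016-2018	2016	2018	6018	30796	6.73	1881
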