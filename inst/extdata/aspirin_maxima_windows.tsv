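entity	t1_label	t2_label	years
Asthma	1986-1990	1966-1970	20
Hypersensitivities, drug	1966-1970	1956-1960	10
Ulcer, gastric	1976-1980	1956-1960	20
Indomethacin	1976-1980	1961-1965	15
Acetaminophen	1981-1985	1971-1975	10
Dipyridamole	1981-1985	1966-1970	15
Vitamin F	1981-1985	1971-1975	10
Adenosine	1971-1975	1966-1970	5
Prostacyclin	1981-1985	1976-1980	5
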