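chr1	0	100	9
chr1	100	200	1
chr1	200	300	9
chr1	300	400	13
chr1	400	500	48
chr1	500	600	52
chr1	600	700	2
chr1	700	800	1
chr1	800	900	1
chr1	900	1000	2
chr1	1000	1100	10
chr1	1100	1200	16
chr1	1200	1300	11
chr1	1300	1400	2
chr1	1400	1500	3
chr1	1500	1600	3
chr1	1600	1700	8
chr1	1700	1800	5
chr1	1800	1900	3
chr1	1900	2000	4
chr1	2000	2100	7
chr1	2100	2200	5
chr1	2200	2300	1
chr1	2300	2400	0
chr1	2400	2500	0
chr1	2500	2600	2
chr1	2600	2700	0
chr1	2700	2800	20
chr1	2800	2900	2
chr1	2900	3000	0
chr1	3000	3100	1
chr1	3100	3200	53
chr1	3200	3300	58
chr1	3300	3400	0
chr1	3400	3500	4
chr1	3500	3600	2
chr1	3600	3700	5
chr1	3700	3800	50
chr1	3800	3900	47
chr1	3900	4000	4
chr1	4000	4100	3
chr1	4100	4200	0
chr1	4200	4300	4
chr1	4300	4400	3
chr1	4400	4500	5
chr1	4500	4600	5
chr1	4600	4700	5
chr1	4700	4800	7
chr1	4800	4900	3
chr1	4900	5000	9
chr1	5000	5100	6
chr1	5100	5200	2
chr1	5200	5300	1
chr1	5300	5400	1
chr1	5400	5500	5
chr1	5500	5600	2
chr1	5600	5700	2
chr1	5700	5800	2
chr1	5800	5900	9
chr1	5900	6000	10
chr1	6000	6100	2
chr1	6100	6200	10
chr1	6200	6300	47
chr1	6300	6400	5
chr1	6400	6500	8
chr1	6500	6600	2
chr1	6600	6700	5
chr1	6700	6800	10
chr1	6800	6900	1
chr1	6900	7000	1
chr1	7000	7100	4
chr1	7100	7200	7
chr1	7200	7300	2
chr1	7300	7400	10
chr1	7400	7500	10
chr1	7500	7600	6
chr1	7600	7700	1
chr1	7700	7800	7
chr1	7800	7900	6
chr1	7900	8000	0
chr1	8000	8100	47
chr1	8100	8200	53
chr2	0	100	4
chr2	100	200	3
chr2	200	300	5
chr2	300	400	1
chr2	400	500	2
chr2	500	600	2
chr2	600	700	1
chr2	700	800	0
chr2	800	900	9
chr2	900	1000	5
chr2	1000	1100	10
chr2	1100	1200	4
chr2	1200	1300	1
chr2	1300	1400	8
chr2	1400	1500	6
chr2	1500	1600	2
chr2	1600	1700	10
chr2	1700	1800	1
chr2	1800	1900	0
chr2	1900	2000	3
chr2	2000	2100	8
chr2	2100	2200	4
chr2	2200	2300	8
chr2	2300	2400	4
chr2	2400	2500	1
chr2	2500	2600	7
chr2	2600	2700	5
chr2	2700	2800	5
chr2	2800	2900	3
chr2	2900	3000	8
chr2	3000	3100	5
chr2	3100	3200	2
chr2	3200	3300	0
chr2	3300	3400	2
chr2	3400	3500	5
chr2	3500	3600	3
chr2	3600	3700	8
chr2	3700	3800	9
chr2	3800	3900	10
chr2	3900	4000	2
chr2	4000	4100	15
chr2	4100	4200	6
chr2	4200	4300	7
chr2	4300	4400	8
chr2	4400	4500	3
chr2	4500	4600	3
chr2	4600	4700	7
chr2	4700	4800	2
chr2	4800	4900	4
chr2	4900	5000	5
chr2	5000	5100	5
chr2	5100	5200	4
chr2	5200	5300	1
chr2	5300	5400	4
chr2	5400	5500	6
chr2	5500	5600	4
chr2	5600	5700	3
chr2	5700	5800	17
chr2	5800	5900	7
chr2	5900	6000	9
chr2	6000	6100	13
chr2	6100	6200	2
chr2	6200	6300	9
chr2	6300	6400	4
chr2	6400	6500	1
chr2	6500	6600	4
chr2	6600	6700	2
chr2	6700	6800	2
chr2	6800	6900	5
chr2	6900	7000	8
chr2	7000	7100	4
chr2	7100	7200	1
chr2	7200	7300	2
chr2	7300	7400	6
chr2	7400	7500	4
chr2	7500	7600	7
chr2	7600	7700	2
chr2	7700	7800	7
chr2	7800	7900	0
chr2	7900	8000	7
chr2	8000	8100	8
chr2	8100	8200	3
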