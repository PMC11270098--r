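# Published top-10 diagnosis-code importance, attribution-based (historical
# impacts). physician_rank is the code's rank in the physician benchmark.
diagnosis	high_ratio_pct	low_ratio_pct	importance_pct	physician_rank
Acute respiratory failure	62.50	0.79	61.71	1
Sepsis	50.00	0.79	49.21	3
Shock, unspecified	47.73	0.00	47.73	4
Pneumonia	34.09	8.66	25.43	2
Acute kidney injury	18.18	0.26	17.92	5
Cardiogenic shock	9.09	0.00	9.09	15
Myocardial infarction	6.82	0.00	6.82	32
Cardiac arrest	6.82	0.26	6.56	11
Gastrointestinal bleeding	10.23	4.46	5.77	12
Aspiration pneumonia	7.95	2.36	5.59	10
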