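# Published top-10 diagnosis-code importance, attribution-based (current
# impacts). physician_rank is the code's rank in the physician benchmark.
diagnosis	high_ratio_pct	low_ratio_pct	importance_pct	physician_rank
Acute respiratory failure	62.41	1.14	61.27	1
Sepsis	36.84	0.76	36.08	3
Pneumonia	42.11	7.20	34.91	2
Shock, unspecified	32.33	0.00	32.33	4
Acute kidney injury	14.29	0.38	13.91	5
Urinary tract infection	16.54	10.61	5.94	365
Hypoxic encephalopathy	5.26	0.38	4.88	14
Hypertension	4.51	1.14	3.37	16
Gastrointestinal bleeding	6.02	2.65	3.36	12
Cardiac arrest	3.01	0.00	3.01	11
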