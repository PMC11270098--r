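# Published top-10 diagnosis-code importance, physician current decisions
# (counts over scale-1 and scale-4 records; ratios printed to 2 decimals,
# percentage scale). Stratum totals are not printed; recoverStratumTotal()
# recovers them from the rows.
diagnosis	count_high	count_low	high_ratio_pct	low_ratio_pct	importance_pct
Acute respiratory failure	199	0	59.58	0.00	59.58
Pneumonia	105	29	31.44	6.40	25.04
Sepsis	86	4	25.75	0.88	24.87
Shock, unspecified	66	0	19.76	0.00	19.76
Acute kidney injury	32	1	9.58	0.22	9.36
Congestive heart failure	37	14	11.08	3.09	7.99
Cardiac arrest	26	0	7.78	0.00	7.78
Aspiration pneumonia	21	3	6.29	0.66	5.63
Cardiogenic shock	17	0	5.09	0.00	5.09
Acute myocardial infarction	17	0	5.09	0.00	5.09
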