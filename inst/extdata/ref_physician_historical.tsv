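# Published top-10 diagnosis-code importance, physician historical decisions.
diagnosis	count_high	count_low	high_ratio_pct	low_ratio_pct	importance_pct
Acute respiratory failure	240	0	49.69	0.00	49.69
Pneumonia	143	6	29.61	4.44	25.16
Sepsis	95	1	19.67	0.74	18.93
Shock, unspecified	78	0	16.15	0.00	16.15
Acute kidney injury	42	0	8.70	0.00	8.70
Congestive heart failure	55	5	11.39	3.70	7.68
Acute exacerbation of chronic obstructive lung disease	35	0	7.25	0.00	7.25
Chronic renal disease	44	4	9.11	2.96	6.15
Chronic lung disease	37	3	7.66	2.22	5.44
Aspiration pneumonia	26	0	5.38	0.00	5.38
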