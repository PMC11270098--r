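# Published bookkeeping counts of a national-claims IHCA cohort (patients with
# >= 1 in-hospital cardiac arrest, procedure codes 99.60/99.63, 2002-2010).
# Raw counts only; derived percentages are recomputed by cohortArithmetic().
count	value
total_records	4622079
analyzed_records	1569478
n_patients	168693
ihca_records	173345
deaths	87311
first_arrest_deaths	82225
single_arrest_patients	164322
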