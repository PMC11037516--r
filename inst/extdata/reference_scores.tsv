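# Published per-drug rank scores from the porcine endoarterial-biopsy PAH
# time course (six approved drugs, days 7/21/60/180 after shunt surgery).
# Used as a fixture for ranking and regimen selection.
drug	drug_class	7	21	60	180
Ambrisentan	era	0.55	1.03	1.55	9.25
Bosentan	era	1.00	1.16	0.34	4.78
Macitentan	era	1.04	1.73	-0.02	1.58
Sildenafil	pde5_inhibitor	1.72	5.33	3.33	19.30
Iloprost	prostacyclin	1.13	0.59	1.17	0.68
Treprostinil	prostacyclin	1.28	2.02	1.10	1.27
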