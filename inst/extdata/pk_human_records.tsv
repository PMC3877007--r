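# Human pharmacokinetic records for the antimalarials in the demonstration
# panel, transcribed from published clinical studies. Where a source reports
# a range the midpoint is stored; half-lives in minutes were converted to h.
compound	dose	Cmax_ng_ml	AUC_ng_h_ml	half_life_h	source
OZ439	50 mg capsule	17	102		Moehrle2013
OZ439	100 mg capsule	34	249		Moehrle2013
OZ439	200 mg capsule	102	890		Moehrle2013
OZ439	400 mg capsule	135	1130		Moehrle2013
OZ439	800 mg capsule	315	3010	27.9	Moehrle2013
OZ439	1200 mg capsule	701	6530	31.6	Moehrle2013
OZ439	400 mg dispersion	566	5430	31.2	Moehrle2013
OZ439	800 mg dispersion	917	9630	25.2	Moehrle2013
OZ439	1600 mg dispersion	1340	17500	30.7	Moehrle2013
OZ439	800 mg dispersion (fed)	2400			Moehrle2013
OZ439	800-1200 mg dispersion	1600			Moehrle2013
OZ277	50 mg	8	40		Valecha2010
OZ277	100 mg	19	105		Valecha2010
OZ277	200 mg	41	239		Valecha2010
OZ277	50 mg (repeat)	14	79		Valecha2010
OZ277	100 mg (repeat)	25	152		Valecha2010
OZ277	200 mg (repeat)	68	408		Valecha2010
ART	120 mg iv	15350	957	0.042	Morris2011
DHA	120 mg iv ART, DHA readout	2130	2571.5	0.68	Morris2011
ART	200 mg po	93	161.5		Morris2011
DHA	200 mg po ART, DHA readout	654	1229		Morris2011
ART	120 mg im	884	999	0.68	Morris2011
DHA	120 mg im ART, DHA readout	1166	2474	1.07	Morris2011
ART	120 mg ir	448	796	0.95	Morris2011
DHA	120 mg ir ART, DHA readout	219	965	1.2	Morris2011
DHA	40 mg	39	98		Morris2011
ART	60 mg	183	155		Morris2011
artemisone	10 mg po	40	30	33.5	Nagelschmitz2008
artemisone	20 mg po	57	66		Nagelschmitz2008
artemisone	30 mg po	51	72		Nagelschmitz2008
artemisone	40 mg po	83	118		Nagelschmitz2008
artemisone	80 mg po	140	282		Nagelschmitz2008
pyrimethamine	75 mg po		36550		Green2007
pyrimethamine	50 mg/d, 3 wk	2059	41800	191	Jacobson2001
pyrimethamine	75 mg single dose	800	106065		Karunajeewa2008
pyrimethamine	25 mg single dose	760	76000	114	Mansor1989
P218	rat 30 mg/kg	6257		7.3	Yuthavong2012
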