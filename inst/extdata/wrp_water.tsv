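parameter	value	sd	unit
temperature	18.1		degC
pH	7.01		
dissolved_oxygen	9.86		mg/L
conductivity	302.1		uS/cm
salinity	0.17		PSU
dry_weight	0.13	0.003	g/L
chlorophyll_a	443.23		ug/L
F	0.00	0.00	mg/L
Cl	26.49	0.21	mg/L
NO2	9.72	0.02	mg/L
SO4	6.00	0.04	mg/L
Br	0.00	0.00	mg/L
NO3	2.59	0.04	mg/L
PO4	6.11	0.02	mg/L
Na	16.85	0.10	mg/L
NH4	0.48	0.02	mg/L
K	4.02	0.06	mg/L
Mg	9.15	0.00	mg/L
Ca	37.42	0.01	mg/L
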