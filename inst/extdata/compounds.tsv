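name	formula	carbons	electrons_per_carbon	molar_mass	mixture
glutamate	C5H9NO4	5	3.6	147.13	FALSE
aspartate	C4H7NO4	4	3	133.1	FALSE
threonine	C4H9NO3	4	4	119.12	FALSE
alanine	C3H7NO2	3	4	89.09	FALSE
glycine	C2H5NO2	2	3	75.07	FALSE
valine	C5H11NO2	5	4.8	117.15	FALSE
leucine	C6H13NO2	6	5	131.17	FALSE
casamino_acids		4	4.2	100	TRUE
ribose	C5H10O5	5	4	150.13	FALSE
glucose	C6H12O6	6	4	180.16	FALSE
succinate	C4H6O4	4	3.5	118.09	FALSE
formate	CH2O2	1	2	46.03	FALSE
co2	CO2	1	0	44.01	FALSE
h2	H2	0	NA	2.016	FALSE
acetate	C2H4O2	2	4	60.05	FALSE
ethanol	C2H6O	2	6	46.07	FALSE
lactate	C3H6O3	3	4	90.08	FALSE
propionate	C3H6O2	3	4.66666666666667	74.08	FALSE
butyrate	C4H8O2	4	5	88.11	FALSE
isobutyrate	C4H8O2	4	5	88.11	FALSE
methylbutyrate	C5H10O2	5	5.2	102.13	FALSE
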