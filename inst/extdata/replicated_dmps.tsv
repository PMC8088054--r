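probe_id	chrom	pos_hg38	gene	discovery_effect	discovery_p	replication_effect	replication_p	combined_effect	combined_p
cg13235761	chr1	203592452	NA	-37.61	4.33e-06	-25.28	5.08e-05	-29.81	1.88e-09
cg26099045	chr2	64064666	NA	14.82	5.74e-06	11.24	1.01e-04	12.81	3.26e-09
cg04428662	chr4	2932461	MFSD10	-30.84	3.21e-06	-34.94	3.43e-07	-32.82	5.51e-12
cg23174201	chr5	151674695	SPARC	-35.83	5.10e-06	-34.87	1.72e-07	-35.27	4.02e-12
cg17170437	chr6	44229461	SLC29A1	-47.62	1.96e-06	-18.62	1.49e-04	-24.24	3.80e-08
cg14871770	chr10	96658622	CYP2C9/CYP2C19	-53.12	1.98e-06	-25.87	1.70e-04	-33.36	1.23e-08
cg02157636	chr11	68709367	TESMIN	-53.21	2.15e-06	-27.25	1.14e-05	-33.33	8.58e-10
cg26039141	chr11	75402116	RPS3	-39.14	3.40e-06	-33.42	1.78e-05	-36.06	2.90e-10
cg22593432	chr13	32001768	NA	-29.91	1.54e-07	-17.66	1.79e-04	-22.64	4.61e-10
cg11789371	chr14	102085048	HSP90AA1	-35.40	4.44e-06	-22.66	3.58e-04	-27.80	1.41e-08
cg05796561	chr18	57128273	NA	-45.24	2.96e-06	-22.91	1.69e-04	-29.24	1.41e-08
cg17944885	chr19	12114920	ZNF20/ZNF788P	-32.71	1.41e-09	-16.34	5.67e-07	-20.72	1.24e-13
cg15787712	chr19	13837429	LOC284454/MIR23	-37.60	6.00e-09	-28.65	2.06e-05	-33.30	9.01e-13
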